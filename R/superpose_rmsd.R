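# Residue correspondence, rigid superposition and per-residue CA RMSD
# profiles: the central readout of every mutagenesis experiment downstream.

#' Map residues between two models by global sequence alignment
#'
#' Aligns `sequence_of(a)` against `sequence_of(b)` with BLOSUM62 and affine
#' gaps (open 11, extend 1; Needleman-Wunsch with end gaps). Aligned
#' non-gap columns become index pairs. Identity is matches over aligned
#' (both non-gap) columns. Author numbering is never compared directly:
#' anchor structures can be N-terminally truncated, so all cross-model
#' correspondence goes through this map.
#'
#' @param a,b `StructureModel`s (or plain character sequences).
#' @return A list of class `ResidueMap`: `pairs` (two-column integer matrix
#'   of indices into a and b), `identity` (fraction in `[0, 1]`).
#' @export
map_residues <- function(a, b) {
  sa <- if (inherits(a, "StructureModel")) sequence_of(a) else as.character(a)
  sb <- if (inherits(b, "StructureModel")) sequence_of(b) else as.character(b)
  if (!nchar(sa) || !nchar(sb)) stop("cannot align an empty sequence")
  if (identical(sa, sb)) {
    n <- nchar(sa)
    return(structure(list(pairs = cbind(a = seq_len(n), b = seq_len(n)),
                          identity = 1), class = "ResidueMap"))
  }
  al <- Biostrings::pairwiseAlignment(
    sa, sb, type = "global",
    substitutionMatrix = blosum62_matrix(),
    gapOpening = 11, gapExtension = 1
  )
  pa <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  pb <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  ia <- cumsum(pa != "-")
  ib <- cumsum(pb != "-")
  both <- pa != "-" & pb != "-"
  pairs <- cbind(a = ia[both], b = ib[both])
  ident <- if (any(both)) mean(pa[both] == pb[both]) else 0
  structure(list(pairs = pairs, identity = ident), class = "ResidueMap")
}

# BLOSUM62 with an X row/column (score 0 vs everything, -1 vs itself is the
# NCBI convention; 0 keeps unknown residues neutral during mapping).
blosum62_matrix <- function() {
  data_env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = data_env)
  m <- data_env$BLOSUM62
  m[rownames(m) %in% c(AA_LETTERS, "X"), colnames(m) %in% c(AA_LETTERS, "X")]
}

#' @export
print.ResidueMap <- function(x, ...) {
  cat("ResidueMap: ", nrow(x$pairs), " aligned pairs, identity ",
      sprintf("%.1f%%", 100 * x$identity), "\n", sep = "")
  invisible(x)
}

#' Percent identity between two sequences
#'
#' Global alignment identity (matches / aligned non-gap columns), reported
#' to 0.1 percent.
#'
#' @param a,b Sequences or `StructureModel`s.
#' @return Percent identity in `[0, 100]`.
#' @export
pairwise_identity <- function(a, b) {
  round(100 * map_residues(a, b)$identity, 1)
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Optimal proper rotation (determinant +1) and translation minimizing the
#' RMSD of `b` onto `a`.
#'
#' @param a,b Numeric n x 3 coordinate matrices, equal length, `n >= 3`.
#' @return List with `rotation` (3 x 3), `translation` (length 3; the
#'   transform is `b %*% rotation + translation`), `rmsd` in Angstroms.
#' @export
kabsch_superpose <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!identical(dim(a), dim(b))) stop("coordinate sets differ in size")
  if (nrow(a) < 3L) stop("need at least 3 points to superpose")
  ca <- colMeans(a); cb <- colMeans(b)
  a0 <- sweep(a, 2, ca); b0 <- sweep(b, 2, cb)
  h <- crossprod(b0, a0)
  sv <- svd(h)
  d <- sign(det(sv$u %*% t(sv$v)))
  rot <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  moved <- b0 %*% rot
  rmsd <- sqrt(mean(rowSums((moved - a0)^2)))
  list(rotation = rot, translation = ca - as.numeric(cb %*% rot),
       rmsd = rmsd)
}

#' Apply a rigid transform to coordinates
#' @param xyz n x 3 matrix.
#' @param fit Result of [kabsch_superpose()].
#' @return Transformed n x 3 matrix.
#' @export
apply_transform <- function(xyz, fit) {
  sweep(as.matrix(xyz) %*% fit$rotation, 2, fit$translation, `+`)
}

#' Per-residue CA deviation profile under one global superposition
#'
#' Superposes the mobile model onto the reference on all mapped CA atoms
#' (single global fit, equal weights -- conformational change is read as
#' large local deviations under that fit, which a windowed fit would erase),
#' then records each mapped mobile residue's Euclidean deviation. Unmapped
#' residues (e.g. opposite a truncated anchor) are reported as `NA`, never
#' zero.
#'
#' @param mobile,reference `StructureModel`s.
#' @param map Optional [map_residues()] result; computed if `NULL`.
#' @param segments Optional [segment_table()] for annotation.
#' @param min_coverage Minimum mapped fraction of mobile residues
#'   (default 0.5); below it an error reports the coverage.
#' @return A `data.frame` of class `RmsdProfile` with columns `resno`,
#'   `aa`, `segment`, `deviation`; attributes `reference_id`, `mobile_id`,
#'   `global_rmsd`, `coverage`.
#' @export
deviation_profile <- function(mobile, reference, map = NULL,
                              segments = NULL, min_coverage = 0.5) {
  stopifnot(inherits(mobile, "StructureModel"),
            inherits(reference, "StructureModel"))
  if (is.null(map)) map <- map_residues(mobile, reference)
  im <- map$pairs[, 1]; ir <- map$pairs[, 2]
  coverage <- length(im) / n_residues(mobile)
  if (coverage < min_coverage)
    stop(sprintf("residue map covers only %.1f%% of mobile residues",
                 100 * coverage))
  fit <- kabsch_superpose(reference$xyz[ir, , drop = FALSE],
                          mobile$xyz[im, , drop = FALSE])
  moved <- apply_transform(mobile$xyz[im, , drop = FALSE], fit)
  dev_mapped <- sqrt(rowSums((moved - reference$xyz[ir, , drop = FALSE])^2))
  deviation <- rep(NA_real_, n_residues(mobile))
  deviation[im] <- dev_mapped
  seg <- if (is.null(segments)) rep(NA_character_, n_residues(mobile)) else
    segment_of(segments, mobile$resno)
  out <- data.frame(resno = mobile$resno, aa = mobile$aa, segment = seg,
                    deviation = deviation, stringsAsFactors = FALSE)
  attr(out, "reference_id") <- reference$model_id
  attr(out, "mobile_id") <- mobile$model_id
  attr(out, "global_rmsd") <- sqrt(mean(dev_mapped^2))
  attr(out, "coverage") <- coverage
  class(out) <- c("RmsdProfile", "data.frame")
  out
}

#' Global RMSD of a deviation profile
#' @param profile An [deviation_profile()] result.
#' @return RMSD in Angstroms.
#' @export
global_rmsd <- function(profile) attr(profile, "global_rmsd")

#' Root-mean-square difference between two deviation profiles
#'
#' Both profiles must share the reference model; the distance is the RMS of
#' the difference of deviations over residues mapped in both.
#'
#' @param p,q `RmsdProfile`s against the same reference.
#' @return Non-negative number.
#' @export
profile_distance <- function(p, q) {
  if (!identical(attr(p, "reference_id"), attr(q, "reference_id")))
    stop("profiles were computed against different references")
  shared <- intersect(p$resno[!is.na(p$deviation)],
                      q$resno[!is.na(q$deviation)])
  if (!length(shared)) stop("profiles have no shared mapped residues")
  dp <- p$deviation[match(shared, p$resno)]
  dq <- q$deviation[match(shared, q$resno)]
  sqrt(mean((dp - dq)^2))
}

#' Write a deviation profile as TSV
#'
#' Columns: residue number, amino acid, segment, deviation (A). A JSON
#' sidecar with the global RMSD and coverage can be produced by
#' [run_pipeline()].
#'
#' @param profile An `RmsdProfile`.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_profile <- function(profile, path) {
  utils::write.table(as.data.frame(profile), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
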