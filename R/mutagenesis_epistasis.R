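# Mutation notation, synapomorphy site registries, mutant sequence
# generation for external structure prediction, and classification of
# predicted mutant models as switched / partial / silent with epistasis
# scores.

# Advanced ColabFold settings used for the IO-state templates; recorded
# verbatim in run manifests as metadata only (this package never runs a
# predictor).
ACF_SETTINGS <- paste(
  "MSA meth Jack hammer, pairwise MSA option 75% coverage, 15% id,",
  "max_msa_clusters = 32, max_extra_msa = 64, no use of ptm sampling,",
  "num_ensembl 1, max_recycle 1, use is-training, num_sample 1,",
  "refine/Amber")

#' Synapomorphy site registry
#'
#' Records the family-diagnostic residues of a template (products of
#' type-ii evolutionary rate shifts between the Slc11 family and its
#' outgroups) and the named mutation combinations assayed on it. Aliases
#' may nest (e.g. `VNT` = `VY` + `YN` + one further substitution).
#'
#' @param template_id Template identifier.
#' @param sites data.frame with columns `segment`, `position`, `wt`,
#'   `outgroup`.
#' @param aliases Named list: label -> character vector of substitution
#'   tokens (`"A131Y"`) and/or other labels.
#' @param segments Optional [segment_table()]; when present every site
#'   must fall inside its named segment.
#' @return A list of class `SynapomorphyRegistry`.
#' @export
synapomorphy_registry <- function(template_id, sites, aliases = list(),
                                  segments = NULL) {
  stopifnot(all(c("segment", "position", "wt", "outgroup") %in%
                  names(sites)))
  if (!is.null(segments)) {
    seg <- segment_of(segments, sites$position)
    bad <- which(is.na(seg) | seg != sites$segment)
    if (length(bad))
      stop("site at position ", sites$position[bad[1]],
           " lies outside its named segment ", sites$segment[bad[1]])
  }
  structure(list(template_id = template_id, sites = sites,
                 aliases = aliases, segments = segments),
            class = "SynapomorphyRegistry")
}

#' Registry for the Q5HQ64 (MCb) template
#'
#' The diagnostic sites are the h1 metal-binding residues D54/N57, h3
#' A131/G135, h6 A228/M231/H233, h7 N277, h10 S393/L397/S398 and h11
#' N442, each paired with its outgroup counterpart. Registered
#' combinations: `YN` (h3), `VY` (h6), `VNT` (= VY + YN + A228T), `ANG`
#' (h10), `Ttg` (h6 + h7 + h11) and the six-fold h3 compound `GYGNGG`
#' (the four glycine positions flanking A131/G135 are synthetic
#' stand-ins: the exact outgroup-invariant positions are figure-only).
#'
#' @return A [synapomorphy_registry()].
#' @export
q5hq64_registry <- function() {
  sites <- data.frame(
    segment = c("h1", "h1", "h3", "h3", "h6", "h6", "h6", "h7",
                "h10", "h10", "h10", "h11"),
    position = c(54L, 57L, 131L, 135L, 228L, 231L, 233L, 277L,
                 393L, 397L, 398L, 442L),
    wt = c("D", "N", "A", "G", "A", "M", "H", "N", "S", "L", "S", "N"),
    outgroup = c("G", "T", "Y", "N", "T", "V", "Y", "T", "A", "N", "G",
                 "G"),
    stringsAsFactors = FALSE)
  aliases <- list(
    YN = c("A131Y", "G135N"),
    VY = c("M231V", "H233Y"),
    VNT = c("VY", "YN", "A228T"),
    ANG = c("S393A", "L397N", "S398G"),
    Ttg = c("A228T", "N277T", "N442G"),
    GYGNGG = c("L128G", "A131Y", "T132G", "G135N", "I136G", "S139G")
  )
  synapomorphy_registry("Q5HQ64", sites, aliases)
}

#' Registry for the A0A149PND7 (MCg1 crown) template
#'
#' Diagnostic sites renumbered for this template (h3 A119/G123, h6
#' A216/M219/H221, h1 D42/N45, h7 N264, h11 N422) plus the h1 suppressor
#' stretch I41/P43/N45/W46 (`NAGI`) and h10 Q374 whose side-chain
#' reduction suppresses the YN-driven switch.
#'
#' @return A [synapomorphy_registry()].
#' @export
a0a149pnd7_registry <- function() {
  sites <- data.frame(
    segment = c("h1", "h1", "h1", "h1", "h1", "h3", "h3", "h6", "h6",
                "h6", "h7", "h10", "h10", "h11"),
    position = c(41L, 42L, 43L, 45L, 46L, 119L, 123L, 216L, 219L, 221L,
                 264L, 370L, 374L, 422L),
    wt = c("I", "D", "P", "N", "W", "A", "G", "A", "M", "H", "N", "L",
           "Q", "N"),
    outgroup = c("N", "G", "A", "G", "I", "Y", "N", "T", "V", "Y", "T",
                 "A", "G", "G"),
    stringsAsFactors = FALSE)
  aliases <- list(
    YN = c("A119Y", "G123N"),
    VY = c("M219V", "H221Y"),
    VNT = c("VY", "YN", "A216T"),
    NAGI = c("I41N", "P43A", "N45G", "W46I")
  )
  synapomorphy_registry("A0A149PND7", sites, aliases)
}

#' Synthetic stand-in template sequence matching a registry
#'
#' Builds a sequence whose residues at registry positions carry the
#' wild-type letters (filler residues cycle through the standard
#' alphabet), long enough to hold every site. Used when the real template
#' sequence is unavailable; clearly a synthetic stand-in.
#'
#' @param registry A [synapomorphy_registry()].
#' @param length Sequence length (default: max site position + 20).
#' @return Character sequence.
#' @export
synthetic_template_for <- function(registry, length = NULL) {
  if (is.null(length)) length <- max(registry$sites$position) + 20L
  aa <- rep_len(AA_LETTERS, length)
  aa[registry$sites$position] <- registry$sites$wt
  # Q5HQ64's GYGNGG stand-in positions carry declared wild types
  for (lab in names(registry$aliases)) {
    toks <- expand_alias(registry, lab)
    for (tk in toks) {
      p <- as.integer(sub("^[A-Z]([0-9]+)[A-Z]$", "\\1", tk))
      aa[p] <- sub("^([A-Z])[0-9]+[A-Z]$", "\\1", tk)
    }
  }
  paste(aa, collapse = "")
}

# Recursively expand an alias into substitution tokens.
expand_alias <- function(registry, label, seen = character(0)) {
  if (label %in% seen) stop("circular alias definition: ", label)
  entry <- registry$aliases[[label]]
  if (is.null(entry)) stop("unknown mutation alias: ", label)
  out <- character(0)
  for (tok in entry) {
    if (grepl("^[A-Z][0-9]+[A-Z]$", tok)) out <- c(out, tok) else
      out <- c(out, expand_alias(registry, tok, c(seen, label)))
  }
  unique(out)
}

#' Parse a mutation specification
#'
#' Accepts whitespace-separated substitution tokens (`"A131Y G135N"`) and
#' registered aliases (`"VNT"`, `"YN ANG"`), expanded against the
#' registry. Wild-type letters are validated against the template
#' sequence.
#'
#' @param text Specification string.
#' @param template Template sequence (character) or `StructureModel`
#'   (validated against author numbering).
#' @param registry Optional [synapomorphy_registry()] providing aliases.
#' @param label Label for the set (default: the input text).
#' @return A list of class `MutationSet`: `label`, `substitutions`
#'   (data.frame `wt`, `position`, `mutant`), `template_id`.
#' @export
parse_mutation_spec <- function(text, template, registry = NULL,
                                label = text) {
  toks <- strsplit(trimws(text), "\\s+")[[1]]
  toks <- toks[nzchar(toks)]
  expanded <- character(0)
  for (tok in toks) {
    if (grepl("^[A-Z][0-9]+[A-Z]$", tok)) {
      expanded <- c(expanded, tok)
    } else if (!is.null(registry) && tok %in% names(registry$aliases)) {
      expanded <- c(expanded, expand_alias(registry, tok))
    } else {
      stop("unknown mutation token or alias: '", tok, "'")
    }
  }
  expanded <- unique(expanded)
  wt <- sub("^([A-Z])[0-9]+[A-Z]$", "\\1", expanded)
  pos <- as.integer(sub("^[A-Z]([0-9]+)[A-Z]$", "\\1", expanded))
  mut <- sub("^[A-Z][0-9]+([A-Z])$", "\\1", expanded)
  if (anyDuplicated(pos))
    stop("duplicate positions in mutation set: ",
         paste(pos[duplicated(pos)], collapse = ", "))
  if (inherits(template, "StructureModel")) {
    idx <- match(pos, template$resno)
    if (anyNA(idx))
      stop("position ", pos[which(is.na(idx))[1]], " absent from template")
    found <- template$aa[idx]
    template_id <- template$model_id
  } else {
    seq_aa <- strsplit(as.character(template), "")[[1]]
    if (any(pos > length(seq_aa)))
      stop("position ", pos[which(pos > length(seq_aa))[1]],
           " beyond template length ", length(seq_aa))
    found <- seq_aa[pos]
    template_id <- if (!is.null(registry)) registry$template_id else
      "template"
  }
  bad <- which(found != wt)
  if (length(bad))
    stop(sprintf(
      "wild-type mismatch at position %d: expected %s, found %s",
      pos[bad[1]], wt[bad[1]], found[bad[1]]))
  ord <- order(pos)
  structure(list(label = label,
                 substitutions = data.frame(wt = wt[ord],
                                            position = pos[ord],
                                            mutant = mut[ord],
                                            stringsAsFactors = FALSE),
                 template_id = template_id),
            class = "MutationSet")
}

#' @export
print.MutationSet <- function(x, ...) {
  s <- x$substitutions
  cat("MutationSet '", x$label, "' on ", x$template_id, ": ",
      paste(paste0(s$wt, s$position, s$mutant), collapse = " "), "\n",
      sep = "")
  invisible(x)
}

#' Apply a mutation set to a template sequence
#'
#' Optionally writes the mutant FASTA (header `template_id|label`) and
#' appends a run-manifest row recording the intended predictor settings.
#'
#' @param template Template sequence (character) or `StructureModel`.
#' @param mset A [parse_mutation_spec()] result.
#' @param fasta Optional FASTA output path.
#' @param manifest Optional manifest TSV path (appended).
#' @param predictor_settings Free-text settings string stored in the
#'   manifest (default: the advanced ColabFold parameter set used for
#'   IO-state modeling, metadata only).
#' @return The mutant sequence (character).
#' @export
apply_mutations <- function(template, mset, fasta = NULL, manifest = NULL,
                            predictor_settings = ACF_SETTINGS) {
  s <- if (inherits(template, "StructureModel")) sequence_of(template) else
    as.character(template)
  aa <- strsplit(s, "")[[1]]
  sub <- mset$substitutions
  if (nrow(sub)) {
    pos <- if (inherits(template, "StructureModel"))
      match(sub$position, template$resno) else sub$position
    if (any(aa[pos] != sub$wt))
      stop("template does not match mutation set wild types")
    aa[pos] <- sub$mutant
  }
  mut_seq <- paste(aa, collapse = "")
  header <- paste0(mset$template_id, "|", mset$label)
  if (!is.null(fasta)) write_fasta(stats::setNames(mut_seq, header), fasta)
  if (!is.null(manifest)) {
    row <- data.frame(
      template = mset$template_id, label = mset$label,
      substitutions = paste(paste0(sub$wt, sub$position, sub$mutant),
                            collapse = " "),
      predictor_settings = predictor_settings, stringsAsFactors = FALSE)
    utils::write.table(row, manifest, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = !file.exists(manifest),
                       append = file.exists(manifest))
  }
  mut_seq
}

#' Broad-scale deviation (BSD) of a mutant profile
#'
#' Fraction of in-scope mapped residues whose deviation from the native
#' model exceeds `tau` Angstroms under one global superposition: the
#' conformation-switch readout. Scope defaults to transmembrane (helix)
#' segments when the profile carries segment annotation, otherwise all
#' mapped residues.
#'
#' @param profile A [deviation_profile()] of mutant vs native.
#' @param tau Deviation threshold in Angstroms (default 2.0).
#' @param scope `"helix"`, `"all"`, or a character vector of segment
#'   names.
#' @return Fraction in `[0, 1]`.
#' @export
broad_scale_deviation <- function(profile, tau = 2.0, scope = "helix") {
  dev <- profile$deviation
  seg <- profile$segment
  in_scope <- if (identical(scope, "all") || all(is.na(seg))) {
    rep(TRUE, length(dev))
  } else if (identical(scope, "helix")) {
    !is.na(seg)
  } else {
    seg %in% scope
  }
  sel <- in_scope & !is.na(dev)
  if (!any(sel)) stop("empty scope: no mapped residues to assess")
  mean(dev[sel] > tau)
}

#' Classify a mutant profile as switched / partial / silent
#'
#' `switched` requires broad-scale deviation at or above
#' `switch_threshold` and, when a signature is supplied, at least 80
#' percent (4 of 5) of the signature segment groups moved (group mean
#' deviation > `tau`): a full conformation switch mobilizes a conserved
#' set of helical segments, not an arbitrary quarter of the structure.
#' `silent` is below `silent_threshold`; anything else is `partial`.
#'
#' @param profile A [deviation_profile()] of mutant vs native.
#' @param label Mutant label for the report.
#' @param tau Per-residue deviation threshold (A).
#' @param switch_threshold,silent_threshold BSD thresholds (defaults 0.25
#'   and 0.05).
#' @param signature Optional list of character vectors of segment names
#'   (the segment groups a true switch must move).
#' @param scope BSD scope, see [broad_scale_deviation()].
#' @return A list of class `SwitchCall`: `label`, `bsd`,
#'   `per_segment_mean`, `signature_hits`, `verdict`, `tau`.
#' @export
classify_switch <- function(profile, label = attr(profile, "mobile_id"),
                            tau = 2.0, switch_threshold = 0.25,
                            silent_threshold = 0.05, signature = NULL,
                            scope = "helix") {
  bsd <- broad_scale_deviation(profile, tau = tau, scope = scope)
  seg_mean <- tapply(profile$deviation, profile$segment, mean,
                     na.rm = TRUE)
  hits <- character(0)
  req <- 0L
  if (!is.null(signature)) {
    group_means <- vapply(signature, function(segs) {
      sel <- profile$segment %in% segs & !is.na(profile$deviation)
      if (!any(sel)) return(NA_real_)
      mean(profile$deviation[sel])
    }, numeric(1))
    hits <- names(signature)[!is.na(group_means) & group_means > tau]
    req <- ceiling(0.8 * length(signature))
  }
  verdict <- if (bsd < silent_threshold) "silent"
  else if (bsd >= switch_threshold &&
           (is.null(signature) || length(hits) >= req)) "switched"
  else "partial"
  structure(list(label = label, bsd = bsd,
                 per_segment_mean = seg_mean,
                 signature_hits = hits, verdict = verdict, tau = tau),
            class = "SwitchCall")
}

#' @export
print.SwitchCall <- function(x, ...) {
  cat("SwitchCall '", x$label, "': ", x$verdict, " (bsd ",
      sprintf("%.3f", x$bsd), ")",
      if (length(x$signature_hits))
        paste0(" [", paste(x$signature_hits, collapse = ","), "]"),
      "\n", sep = "")
  invisible(x)
}

#' Epistasis score of a mutation pair
#'
#' `epsilon = bsd(A+B) - bsd(A) - bsd(B)`. Positive beyond the band means
#' the combination triggers deviation its parts do not (cooperative);
#' negative beyond the band means the parts' effects cancel
#' (antagonistic); within the band, additive.
#'
#' @param call_a,call_b,call_ab `SwitchCall`s for the two singles and the
#'   combination, all against the same native reference.
#' @param band Additivity tolerance band (default 0.10).
#' @return A list of class `EpistasisScore`: `labels`, `epsilon`,
#'   `classification`.
#' @export
epistasis_score <- function(call_a, call_b, call_ab, band = 0.10) {
  eps <- call_ab$bsd - call_a$bsd - call_b$bsd
  cls <- if (eps > band) "cooperative" else if (eps < -band)
    "antagonistic" else "additive"
  structure(list(labels = c(call_a$label, call_b$label),
                 combined = call_ab$label, epsilon = eps,
                 classification = cls, band = band),
            class = "EpistasisScore")
}

#' @export
print.EpistasisScore <- function(x, ...) {
  cat("Epistasis ", x$labels[1], " x ", x$labels[2], ": epsilon = ",
      sprintf("%+.3f", x$epsilon), " (", x$classification, ")\n", sep = "")
  invisible(x)
}

#' Screen candidate suppressors of a conformation switch
#'
#' For each candidate, the suppression strength is the drop in
#' broad-scale deviation when the candidate is combined with the
#' switching mutation set: `bsd(switching) - bsd(switching + candidate)`.
#' Candidates are ranked by descending suppression.
#'
#' @param switch_call `SwitchCall` of the switching set alone (verdict
#'   must be `switched`).
#' @param combined_calls Named list of `SwitchCall`s for switching set +
#'   candidate (names = candidate labels).
#' @return data.frame `candidate`, `bsd_combined`, `suppression`, ranked.
#' @export
suppressor_screen <- function(switch_call, combined_calls) {
  if (switch_call$verdict != "switched")
    stop("the switching set must itself be classified as switched")
  df <- data.frame(
    candidate = names(combined_calls),
    bsd_combined = vapply(combined_calls, function(x) x$bsd, numeric(1)),
    stringsAsFactors = FALSE)
  df$suppression <- switch_call$bsd - df$bsd_combined
  df <- df[order(-df$suppression), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write switch calls as a TSV report
#'
#' @param calls List of `SwitchCall`s.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_switch_report <- function(calls, path) {
  df <- do.call(rbind, lapply(calls, function(x)
    data.frame(label = x$label, bsd = round(x$bsd, 4),
               verdict = x$verdict,
               signature_hits = paste(x$signature_hits, collapse = ","),
               tau = x$tau, stringsAsFactors = FALSE)))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
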