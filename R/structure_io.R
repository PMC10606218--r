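# Three-letter -> one-letter amino acid code. Non-standard residues map to X
# (retained with their coordinates so profiles stay index-complete).
AA3TO1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V"
)

AA_LETTERS <- unname(AA3TO1)

#' Construct a single-chain CA structure model
#'
#' The central container of the package: an ordered CA trace with author
#' residue numbering, one-letter residue identities and an optional
#' per-residue confidence score (e.g. AlphaFold pLDDT read from the PDB
#' B-factor column).
#'
#' @param model_id Character scalar identifying the model.
#' @param resno Integer vector of author residue numbers, strictly
#'   increasing.
#' @param aa Character vector of one-letter residue codes (20 standard
#'   letters or `"X"`).
#' @param xyz Numeric matrix (n x 3) of CA coordinates in Angstroms.
#' @param confidence Optional numeric vector in `[0, 100]`, one value per
#'   residue, or `NULL`.
#' @param source_tag Character tag recording provenance (`"PDB"`, `"AF2"`,
#'   `"CFpdb"`, `"CFnt"`, `"aCF"`, `"synthetic"`, ...).
#' @return An object of class `StructureModel`.
#' @export
structure_model <- function(model_id, resno, aa, xyz,
                            confidence = NULL, source_tag = "unknown") {
  resno <- as.integer(resno)
  xyz <- as.matrix(xyz)
  storage.mode(xyz) <- "double"
  n <- length(resno)
  if (n == 0L) stop("structure model must contain at least one residue")
  if (length(aa) != n || nrow(xyz) != n || ncol(xyz) != 3L)
    stop("resno, aa and xyz dimensions disagree")
  if (any(diff(resno) <= 0L)) {
    bad <- resno[which(diff(resno) <= 0L)[1] + 1L]
    stop("residue numbers must be strictly increasing (offending residue ",
         bad, ")")
  }
  if (!all(is.finite(xyz))) stop("all CA coordinates must be finite")
  aa <- unname(toupper(aa))
  aa[!aa %in% c(AA_LETTERS, "X")] <- "X"
  if (!is.null(confidence)) {
    if (length(confidence) != n) stop("confidence length must match residues")
    confidence <- unname(as.numeric(confidence))
  }
  dimnames(xyz) <- NULL
  structure(
    list(model_id = as.character(model_id), resno = resno, aa = aa,
         xyz = xyz, confidence = confidence,
         source_tag = as.character(source_tag)),
    class = "StructureModel"
  )
}

#' @export
print.StructureModel <- function(x, ...) {
  cat("StructureModel '", x$model_id, "' (", x$source_tag, "): ",
      length(x$resno), " residues, numbering ", x$resno[1], "-",
      x$resno[length(x$resno)], "\n", sep = "")
  invisible(x)
}

#' Number of residues in a model
#' @param model A `StructureModel`.
#' @return Integer residue count.
#' @export
n_residues <- function(model) length(model$resno)

#' Read a CA trace from a PDB-format file
#'
#' Parses fixed-column `ATOM`/`HETATM` records and keeps CA atoms of the
#' first model and first chain encountered. Alternate locations are resolved
#' to the highest occupancy (ties: first seen). The B-factor column is kept
#' as the per-residue confidence (AlphaFold models store pLDDT there).
#'
#' @param path Path to a PDB-format text file with at least one CA record.
#' @param model_id Identifier for the returned model; defaults to the file
#'   name without extension.
#' @param source_tag Provenance tag, default `"PDB"`.
#' @return A [structure_model()].
#' @export
read_structure <- function(path, model_id = NULL, source_tag = "PDB") {
  if (is.null(model_id))
    model_id <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  # truncate at the first ENDMDL so only model 1 is read
  endmdl <- grep("^ENDMDL", lines)
  if (length(endmdl)) lines <- lines[seq_len(endmdl[1] - 1L)]
  rec <- lines[startsWith(lines, "ATOM") | startsWith(lines, "HETATM")]
  if (!length(rec)) stop("no CA atom records found in ", path)
  atom_name <- trimws(substr(rec, 13, 16))
  rec <- rec[atom_name == "CA"]
  if (!length(rec)) stop("no CA atom records found in ", path)
  chain <- substr(rec, 22, 22)
  rec <- rec[chain == chain[1]]
  altloc <- substr(rec, 17, 17)
  resname <- trimws(substr(rec, 18, 20))
  resno <- suppressWarnings(as.integer(substr(rec, 23, 26)))
  if (anyNA(resno)) stop("unparseable residue number in ", path)
  x <- as.numeric(substr(rec, 31, 38))
  y <- as.numeric(substr(rec, 39, 46))
  z <- as.numeric(substr(rec, 47, 54))
  occ <- suppressWarnings(as.numeric(substr(rec, 55, 60)))
  occ[is.na(occ)] <- 1
  bf <- suppressWarnings(as.numeric(substr(rec, 61, 66)))
  # resolve altlocs: highest occupancy, ties broken by file order
  keep <- rep(TRUE, length(rec))
  for (rn in unique(resno[duplicated(resno)])) {
    idx <- which(resno == rn)
    if (length(unique(altloc[idx])) > 1L) {
      best <- idx[which.max(occ[idx])]
      keep[setdiff(idx, best)] <- FALSE
    } else {
      stop("duplicate CA records for residue ", rn, " in ", path)
    }
  }
  resno <- resno[keep]; resname <- resname[keep]
  x <- x[keep]; y <- y[keep]; z <- z[keep]; bf <- bf[keep]
  if (is.unsorted(resno, strictly = TRUE)) {
    bad <- resno[which(diff(resno) <= 0L)[1] + 1L]
    stop("non-monotonic residue numbering at residue ", bad, " in ", path)
  }
  aa <- AA3TO1[resname]
  aa[is.na(aa)] <- "X"
  conf <- if (all(is.na(bf))) NULL else ifelse(is.na(bf), 0, bf)
  structure_model(model_id, resno, aa, cbind(x, y, z),
                  confidence = conf, source_tag = source_tag)
}

#' Write a model as a CA-only PDB file
#'
#' Fixed-column `ATOM` records, chain A, coordinates to three decimals.
#' Confidence (if present) goes to the B-factor column.
#'
#' @param model A `StructureModel`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_structure <- function(model, path) {
  stopifnot(inherits(model, "StructureModel"))
  aa3 <- names(AA3TO1)[match(model$aa, AA3TO1)]
  aa3[is.na(aa3)] <- "UNK"
  bf <- if (is.null(model$confidence)) rep(0, n_residues(model)) else
    model$confidence
  lines <- sprintf(
    "ATOM  %5d  CA  %3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
    seq_len(n_residues(model)), aa3, model$resno,
    model$xyz[, 1], model$xyz[, 2], model$xyz[, 3], 1, bf
  )
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' One-letter sequence of a model
#'
#' Concatenates residue letters in order; gaps in author numbering do not
#' insert characters.
#'
#' @param model A `StructureModel`.
#' @return A single character string.
#' @export
sequence_of <- function(model) {
  stopifnot(inherits(model, "StructureModel"))
  if (n_residues(model) == 0L) stop("empty model")
  paste(model$aa, collapse = "")
}

#' Build a helix/loop segment table
#'
#' Segments annotate deviation profiles and site registries with the
#' transmembrane-helix nomenclature of the LeuT fold (h1...h11, split
#' helices h1a/h1b, h6a/h6b, and inter-helix loops such as "l5/6").
#'
#' @param name Character vector of unique segment names.
#' @param start,end Integer author residue numbers, `start <= end`.
#' @param class `"helix"` or `"loop"` per segment.
#' @return A `data.frame` of class `SegmentTable`.
#' @export
segment_table <- function(name, start, end, class = "helix") {
  df <- data.frame(name = as.character(name), start = as.integer(start),
                   end = as.integer(end),
                   class = rep_len(as.character(class), length(name)),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$name)) stop("segment names must be unique")
  if (any(df$start > df$end)) stop("segment start must be <= end")
  df <- df[order(df$start), , drop = FALSE]
  if (nrow(df) > 1L && any(df$start[-1] <= df$end[-nrow(df)]))
    stop("segments must not overlap")
  if (!all(df$class %in% c("helix", "loop")))
    stop("segment class must be 'helix' or 'loop'")
  rownames(df) <- NULL
  class(df) <- c("SegmentTable", "data.frame")
  df
}

#' Read a segment table from TSV
#'
#' Expects columns `name`, `start`, `end` and optionally `class`.
#'
#' @param path TSV file path.
#' @return A [segment_table()].
#' @export
read_segment_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("name", "start", "end") %in% names(df)))
    stop("segment table needs columns name, start, end")
  if (is.null(df$class)) df$class <- "helix"
  segment_table(df$name, df$start, df$end, df$class)
}

#' Segment name for each residue number
#'
#' @param segments A [segment_table()].
#' @param resno Integer vector of residue numbers.
#' @return Character vector of segment names (`NA` outside all segments).
#' @export
segment_of <- function(segments, resno) {
  out <- rep(NA_character_, length(resno))
  for (i in seq_len(nrow(segments))) {
    hit <- resno >= segments$start[i] & resno <= segments$end[i]
    out[hit] <- segments$name[i]
  }
  out
}

#' Write sequences as FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line width, default 60.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path, width = 60) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

#' Read a FASTA file as a named character vector
#'
#' @param path FASTA file path.
#' @return Named character vector (names = headers up to first whitespace).
#' @export
read_fasta <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  hdr <- grepl("^>", lines)
  if (!any(hdr)) stop("no FASTA headers in ", path)
  idx <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], idx[!hdr]),
                 paste, character(1), collapse = "")
  names(seqs) <- sub("^>(\\S+).*$", "\\1", lines[hdr])
  seqs
}
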