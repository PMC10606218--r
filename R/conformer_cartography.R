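# All-against-all structural comparison with a Dali-style elastic
# distance-matrix score, correspondence-analysis embedding, OO/IO state
# assignment against anchor structures, and ordering of conformers along
# the transition path.

#' Parameters of the elastic distance-matrix similarity score
#'
#' @param theta Unitless similarity threshold (default 0.2): residue pairs
#'   whose intramolecular distances agree better than `theta` (relative)
#'   add to the score, worse-agreeing pairs subtract.
#' @param envelope_scale Distance envelope in Angstroms (default 20):
#'   long-range pairs are down-weighted by `exp(-(d*/envelope)^2)`.
#' @param max_pair_distance Optional hard cap in Angstroms on the mean
#'   intramolecular distance of scored pairs (`NULL` = none).
#' @return A list of class `ElasticScoreParams`.
#' @export
elastic_params <- function(theta = 0.2, envelope_scale = 20,
                           max_pair_distance = NULL) {
  if (theta <= 0 || envelope_scale <= 0)
    stop("theta and envelope_scale must be positive")
  structure(list(theta = theta, envelope_scale = envelope_scale,
                 max_pair_distance = max_pair_distance),
            class = "ElasticScoreParams")
}

#' Elastic distance-matrix similarity between two models
#'
#' Superposition-free score over the sequence-aligned residue
#' correspondence: for every mapped residue pair (i < j),
#' `(theta - |d_ij^A - d_ij^B| / d*_ij) * exp(-(d*_ij / envelope)^2)`
#' where `d_ij` are intramolecular CA distances and `d*_ij` their mean;
#' the i = j terms contribute `theta` each. Identical structures attain
#' the maximum for their size.
#'
#' @param a,b `StructureModel`s.
#' @param map Optional [map_residues()] result (computed if `NULL`).
#' @param params An [elastic_params()].
#' @return Numeric similarity score.
#' @export
elastic_similarity <- function(a, b, map = NULL, params = elastic_params()) {
  if (is.null(map)) map <- map_residues(a, b)
  m <- nrow(map$pairs)
  if (m < 3L) stop("need at least 3 mapped residue pairs")
  da <- as.matrix(stats::dist(a$xyz[map$pairs[, 1], , drop = FALSE]))
  db <- as.matrix(stats::dist(b$xyz[map$pairs[, 2], , drop = FALSE]))
  ut <- upper.tri(da)
  dstar <- (da[ut] + db[ut]) / 2
  wt <- exp(-(dstar / params$envelope_scale)^2)
  term <- (params$theta - abs(da[ut] - db[ut]) / dstar) * wt
  if (!is.null(params$max_pair_distance))
    term <- term[dstar <= params$max_pair_distance]
  sum(term) + m * params$theta
}

#' All-against-all elastic similarity of a model pool
#'
#' Computes every pairwise elastic similarity (correspondences via
#' [map_residues()]) and normalizes scores Z-like against the pool itself:
#' `(S - m(L)) / s(L)` where `m`, `s` are the mean and s.d. of raw scores
#' in size bins of the aligned length `L` (pairs of near-identical length
#' all share one bin). Anchors must be members of the pool.
#'
#' @param models Named list of `StructureModel`s (>= 3).
#' @param oo,io Model ids of the outward-open and inward-open anchors.
#' @param params An [elastic_params()].
#' @param n_bins Number of size bins for the normalization (collapsed if
#'   the pool spans few sizes).
#' @return An object of class `ConformerMap`: `model_ids`, `similarity`
#'   (normalized, symmetric), `raw_similarity`, `anchors`; embedding,
#'   state calls and transition order are filled by the dedicated
#'   functions.
#' @export
aaa_matrix <- function(models, oo, io, params = elastic_params(),
                       n_bins = 3) {
  ids <- names(models)
  if (is.null(ids) || any(!nzchar(ids)))
    stop("models must be a named list")
  n <- length(models)
  if (n < 3L) stop("need at least 3 models")
  if (!all(c(oo, io) %in% ids)) stop("both anchors must be in the pool")
  s <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  len <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) {
    for (j in i:n) {
      map <- map_residues(models[[i]], models[[j]])
      if (nrow(map$pairs) < 3L)
        stop("fewer than 3 mapped residues between ", ids[i], " and ",
             ids[j])
      s[i, j] <- s[j, i] <- elastic_similarity(models[[i]], models[[j]],
                                               map, params)
      len[i, j] <- len[j, i] <- nrow(map$pairs)
    }
  }
  # pool-internal Z-like normalization in size bins of aligned length
  off <- upper.tri(s)
  lens <- len[off]
  breaks <- unique(stats::quantile(lens, probs = seq(0, 1,
                                                     length.out = n_bins + 1)))
  bin_of <- function(l) {
    if (length(breaks) <= 2L) rep(1L, length(l)) else
      as.integer(cut(l, breaks, include.lowest = TRUE))
  }
  bins <- bin_of(lens)
  mu <- tapply(s[off], bins, mean)
  sdv <- tapply(s[off], bins, stats::sd)
  sdv[!is.finite(sdv) | sdv == 0] <- 1
  z <- s
  allbin <- bin_of(as.numeric(len))
  z[] <- (as.numeric(s) - as.numeric(mu)[allbin]) / as.numeric(sdv)[allbin]
  structure(list(model_ids = ids, similarity = z, raw_similarity = s,
                 aligned_length = len, anchors = c(oo = oo, io = io),
                 params = params, embedding = NULL, state_calls = NULL,
                 transition_order = NULL),
            class = "ConformerMap")
}

#' @export
print.ConformerMap <- function(x, ...) {
  cat("ConformerMap: ", length(x$model_ids), " models; anchors OO='",
      x$anchors[["oo"]], "', IO='", x$anchors[["io"]], "'",
      if (!is.null(x$embedding)) "; embedded",
      if (!is.null(x$state_calls)) "; states assigned", "\n", sep = "")
  invisible(x)
}

# Canonicalize axis signs: the largest-magnitude coordinate positive.
canonicalize_signs <- function(emb) {
  for (k in seq_len(ncol(emb))) {
    i <- which.max(abs(emb[, k]))
    if (emb[i, k] < 0) emb[, k] <- -emb[, k]
  }
  emb
}

#' Correspondence-analysis embedding of a conformer map
#'
#' Shifts the normalized similarity matrix to be non-negative, then runs
#' two-dimensional correspondence analysis (SVD of the standardized
#' residuals of the row/column profiles). Axis signs are canonicalized so
#' the largest-magnitude coordinate on each axis is positive.
#'
#' @param cmap A [aaa_matrix()] result.
#' @return The `ConformerMap` with `embedding` filled (n x 2 matrix of
#'   principal coordinates).
#' @export
correspondence_embed <- function(cmap) {
  stopifnot(inherits(cmap, "ConformerMap"))
  m <- cmap$similarity - min(cmap$similarity)
  if (sum(m) <= 0) stop("degenerate similarity matrix")
  p <- m / sum(m)
  r <- rowSums(p)
  cc <- colSums(p)
  if (any(r == 0) | any(cc == 0))
    stop("rank deficiency after centering; consider MDS on dissimilarity")
  e <- (p - outer(r, cc)) / sqrt(outer(r, cc))
  sv <- svd(e)
  pos <- sum(sv$d > max(sv$d) * 1e-10)
  if (pos < 2L)
    stop("similarity matrix has rank < 2 after centering; ",
         "consider MDS on dissimilarity instead")
  emb <- sweep(sv$u[, 1:2, drop = FALSE], 2, sv$d[1:2], `*`) / sqrt(r)
  rownames(emb) <- cmap$model_ids
  colnames(emb) <- c("axis1", "axis2")
  cmap$embedding <- canonicalize_signs(emb)
  cmap
}

#' Assign OO / IO / intermediate states against the anchors
#'
#' After shifting similarities non-negative, each model's margin is
#' `(sim_to_OO - sim_to_IO) / (sim_to_OO + sim_to_IO)`, in `[-1, 1]`.
#' Calls are OO for margin >= +delta, IO for <= -delta, else intermediate.
#'
#' The default band `delta = 0.05` suits heterogeneous pools where only
#' near-tied models should count as intermediate. For an interpolated
#' rocking-bundle series the margin is close to `1 - 2t`, so a band
#' mirroring a `t in (1/3, 2/3)` intermediate definition is
#' `delta = 1/3`.
#'
#' @param cmap A `ConformerMap`.
#' @param delta Margin half-band for the intermediate call.
#' @return The `ConformerMap` with `state_calls`: data.frame `model_id`,
#'   `margin`, `state`.
#' @export
assign_states <- function(cmap, delta = 0.05) {
  stopifnot(inherits(cmap, "ConformerMap"))
  oo <- cmap$anchors[["oo"]]; io <- cmap$anchors[["io"]]
  if (!all(c(oo, io) %in% cmap$model_ids)) stop("anchor missing from pool")
  s <- cmap$similarity - min(cmap$similarity)
  soo <- s[, oo]; sio <- s[, io]
  # a model's own anchor column contains the (shifted) self-similarity,
  # which dominates correctly for the anchors themselves
  margin <- (soo - sio) / pmax(soo + sio, .Machine$double.eps)
  state <- ifelse(margin >= delta, "OO",
                  ifelse(margin <= -delta, "IO", "intermediate"))
  cmap$state_calls <- data.frame(model_id = cmap$model_ids,
                                 margin = as.numeric(margin),
                                 state = state, stringsAsFactors = FALSE)
  cmap
}

#' Order models along the OO -> IO transition path
#'
#' Projects each model's embedding onto the chord joining the two anchor
#' embeddings and ranks models by that projection (OO anchor first). Ties
#' are broken by similarity to the OO anchor (closer first).
#'
#' @param cmap A `ConformerMap` with embedding (computed if absent).
#' @return The `ConformerMap` with `transition_order` (character vector of
#'   model ids from OO-like to IO-like).
#' @export
order_transition <- function(cmap) {
  stopifnot(inherits(cmap, "ConformerMap"))
  if (is.null(cmap$embedding)) cmap <- correspondence_embed(cmap)
  oo <- cmap$anchors[["oo"]]; io <- cmap$anchors[["io"]]
  emb <- cmap$embedding
  chord <- emb[io, ] - emb[oo, ]
  nc <- sqrt(sum(chord^2))
  if (nc == 0) stop("anchor embeddings coincide")
  proj <- as.numeric((emb - matrix(emb[oo, ], nrow(emb), 2,
                                   byrow = TRUE)) %*% (chord / nc))
  tie <- -cmap$similarity[, oo]
  ord <- order(proj, tie)
  cmap$transition_order <- cmap$model_ids[ord]
  cmap
}

#' Run the full cartography of a model pool
#'
#' Convenience wrapper: [aaa_matrix()] + [correspondence_embed()] +
#' [assign_states()] + [order_transition()].
#'
#' @inheritParams aaa_matrix
#' @inheritParams assign_states
#' @return A fully populated `ConformerMap`.
#' @export
cartography <- function(models, oo, io, params = elastic_params(),
                        delta = 0.05) {
  cmap <- aaa_matrix(models, oo, io, params)
  cmap <- correspondence_embed(cmap)
  cmap <- assign_states(cmap, delta = delta)
  order_transition(cmap)
}

#' Write cartography results as TSV
#'
#' Writes the similarity matrix and a per-model table (axis1, axis2,
#' state, margin, transition rank).
#'
#' @param cmap A populated `ConformerMap`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cartography <- function(cmap, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, "similarity_matrix.tsv")
  utils::write.table(round(cmap$similarity, 6), p1, sep = "\t",
                     quote = FALSE, col.names = NA)
  tab <- data.frame(model_id = cmap$model_ids,
                    axis1 = round(cmap$embedding[, 1], 6),
                    axis2 = round(cmap$embedding[, 2], 6),
                    state = cmap$state_calls$state,
                    margin = round(cmap$state_calls$margin, 6),
                    transition_rank = match(cmap$model_ids,
                                            cmap$transition_order),
                    stringsAsFactors = FALSE)
  p2 <- file.path(dir, "conformer_map.tsv")
  utils::write.table(tab, p2, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(p1, p2))
}
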