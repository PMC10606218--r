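# Protein-structure networks at the CA level: interaction-strength graphs,
# per-state consensus networks, community detection and state-vs-state
# comparison.

#' Per-amino-acid normalization factors for PSN interaction strengths
#'
#' The interaction strength of a residue pair is normalized by the typical
#' contact capacity of its amino-acid types. Capacities are estimated from
#' the analysed pool itself (deterministic given the pool): the mean
#' contact count of each residue type, floored at 1 so types never seen in
#' contact do not blow up the normalization.
#'
#' @param models List of `StructureModel`s (the pool).
#' @param contact_cutoff CA contact cutoff in Angstroms.
#' @param min_separation Minimum sequence separation |i - j| for a contact.
#' @return Named numeric vector of capacities per residue letter.
#' @export
psn_norm_factors <- function(models, contact_cutoff = 5.0,
                             min_separation = 3L) {
  if (inherits(models, "StructureModel")) models <- list(models)
  counts <- list()
  for (m in models) {
    d <- as.matrix(stats::dist(m$xyz))
    sep <- abs(outer(m$resno, m$resno, `-`))
    adj <- d <= contact_cutoff & sep >= min_separation
    counts[[length(counts) + 1L]] <-
      data.frame(aa = m$aa, k = rowSums(adj), stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, counts)
  cap <- tapply(df$k, df$aa, mean)
  out <- stats::setNames(rep(1, length(c(AA_LETTERS, "X"))),
                         c(AA_LETTERS, "X"))
  out[names(cap)] <- pmax(as.numeric(cap), 1)
  out
}

#' Build a residue-interaction network from a CA model
#'
#' Contacts are CA pairs within `contact_cutoff` Angstroms and at least
#' `min_separation` residues apart in sequence (suppressing trivial
#' backbone contacts). Interaction strength is
#' `I_ij = 100 * n_ij / sqrt(N_i * N_j)` with `n_ij` the 0/1 contact
#' indicator and `N_x` the pool-derived contact capacity of type `x`
#' ([psn_norm_factors()]); edges with `I_ij < i_min` are pruned.
#'
#' @param model A `StructureModel` (>= 10 residues).
#' @param contact_cutoff CA cutoff in Angstroms (default 5.0; a CA-level
#'   proxy for heavy-atom contact definitions, configurable up to ~8).
#' @param i_min Pruning threshold on interaction strength (default 3.0).
#' @param norm Optional named capacity vector (defaults to factors
#'   computed from this model alone).
#' @param min_separation Minimum |i - j| (default 3).
#' @return A list of class `PSNGraph`: `nodes` (residue numbers with >= 1
#'   retained edge), `edges` (data.frame `i`, `j`, `strength` keyed by
#'   residue number), plus the parameters used.
#' @export
build_psn <- function(model, contact_cutoff = 5.0, i_min = 3.0,
                      norm = NULL, min_separation = 3L) {
  stopifnot(inherits(model, "StructureModel"))
  if (n_residues(model) < 10L) stop("model too small for a PSN")
  if (is.null(norm))
    norm <- psn_norm_factors(model, contact_cutoff, min_separation)
  d <- as.matrix(stats::dist(model$xyz))
  if (any(d[upper.tri(d)] == 0))
    stop("degenerate coordinates: coincident CA atoms")
  sep <- abs(outer(model$resno, model$resno, `-`))
  adj <- d <= contact_cutoff & sep >= min_separation & upper.tri(d)
  idx <- which(adj, arr.ind = TRUE)
  if (nrow(idx)) {
    ni <- norm[model$aa[idx[, 1]]]
    nj <- norm[model$aa[idx[, 2]]]
    strength <- 100 / sqrt(ni * nj)
    keep <- strength >= i_min
    edges <- data.frame(i = model$resno[idx[keep, 1]],
                        j = model$resno[idx[keep, 2]],
                        strength = as.numeric(strength[keep]))
    edges <- edges[order(edges$i, edges$j), , drop = FALSE]
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(i = integer(0), j = integer(0),
                        strength = numeric(0))
  }
  structure(list(nodes = sort(unique(c(edges$i, edges$j))), edges = edges,
                 i_min = i_min, contact_cutoff = contact_cutoff,
                 norm = norm, model_id = model$model_id),
            class = "PSNGraph")
}

#' @export
print.PSNGraph <- function(x, ...) {
  cat("PSNGraph (", x$model_id, "): ", length(x$nodes), " nodes, ",
      nrow(x$edges), " edges (cutoff ", x$contact_cutoff, " A, i_min ",
      x$i_min, ")\n", sep = "")
  invisible(x)
}

psn_edge_keys <- function(g) paste(g$edges$i, g$edges$j, sep = "-")

#' Consensus network over an ensemble of PSNs
#'
#' An edge is retained iff present in at least `occupancy` of the input
#' graphs; its consensus strength is the mean over the graphs containing
#' it. Graphs whose numbering differs from the reference can be remapped
#' first through `maps` (one [map_residues()]-style `ResidueMap` per
#' graph, pairing graph numbering to reference numbering).
#'
#' @param graphs List of >= 2 `PSNGraph`s.
#' @param occupancy Minimum fraction of graphs containing the edge
#'   (default 0.5); `1.0` gives the edge-set intersection.
#' @param maps Optional list of `ResidueMap`s onto reference numbering.
#' @return A `PSNGraph` holding the consensus.
#' @export
consensus_network <- function(graphs, occupancy = 0.5, maps = NULL) {
  if (length(graphs) < 2L) stop("need at least 2 graphs")
  if (!is.null(maps)) {
    graphs <- Map(function(g, mp) {
      lut <- stats::setNames(mp$pairs[, 2], mp$pairs[, 1])
      g$edges$i <- as.integer(lut[as.character(g$edges$i)])
      g$edges$j <- as.integer(lut[as.character(g$edges$j)])
      keep <- !is.na(g$edges$i) & !is.na(g$edges$j)
      g$edges <- g$edges[keep, , drop = FALSE]
      swap <- g$edges$i > g$edges$j
      tmp <- g$edges$i[swap]
      g$edges$i[swap] <- g$edges$j[swap]
      g$edges$j[swap] <- tmp
      g
    }, graphs, maps)
  }
  all_edges <- do.call(rbind, lapply(graphs, function(g)
    g$edges[, c("i", "j", "strength")]))
  if (nrow(all_edges) == 0L) {
    cons <- data.frame(i = integer(0), j = integer(0),
                       strength = numeric(0))
  } else {
    key <- paste(all_edges$i, all_edges$j, sep = "-")
    cnt <- table(key)
    keep_keys <- names(cnt)[cnt / length(graphs) >= occupancy]
    if (!length(keep_keys)) {
      cons <- data.frame(i = integer(0), j = integer(0),
                         strength = numeric(0))
    } else {
      sel <- all_edges[key %in% keep_keys, , drop = FALSE]
      selkey <- paste(sel$i, sel$j, sep = "-")
      cons <- do.call(rbind, lapply(split(sel, selkey), function(df)
        data.frame(i = df$i[1], j = df$j[1],
                   strength = mean(df$strength))))
      cons <- cons[order(cons$i, cons$j), , drop = FALSE]
      rownames(cons) <- NULL
    }
  }
  structure(list(nodes = sort(unique(c(cons$i, cons$j))), edges = cons,
                 i_min = graphs[[1]]$i_min,
                 contact_cutoff = graphs[[1]]$contact_cutoff,
                 norm = graphs[[1]]$norm,
                 model_id = sprintf("consensus(%d graphs, occ %.2f)",
                                    length(graphs), occupancy)),
            class = "PSNGraph")
}

#' Detect residue communities in a PSN
#'
#' Connected components of the pruned graph; components larger than
#' `split_above` nodes are further split by greedy modularity
#' optimization (deterministic). Communities smaller than `min_size`
#' members are dropped. When a segment table is supplied each community is
#' labeled by the segments it touches.
#'
#' @param g A `PSNGraph`.
#' @param segments Optional [segment_table()].
#' @param min_size Minimum community size (default 3).
#' @param split_above Split components larger than this (default 30).
#' @return List of `Community` objects: `id`, `members` (residue numbers),
#'   `segments_touched`.
#' @export
detect_communities <- function(g, segments = NULL, min_size = 3L,
                               split_above = 30L) {
  stopifnot(inherits(g, "PSNGraph"))
  if (nrow(g$edges) == 0L) return(list())
  ig <- igraph::graph_from_data_frame(
    data.frame(from = as.character(g$edges$i),
               to = as.character(g$edges$j),
               weight = g$edges$strength),
    directed = FALSE)
  comp <- igraph::components(ig)
  groups <- split(igraph::V(ig)$name, comp$membership)
  out_members <- list()
  for (grp in groups) {
    if (length(grp) > split_above) {
      sub <- igraph::induced_subgraph(ig, grp)
      cl <- igraph::cluster_fast_greedy(sub)
      out_members <- c(out_members,
                       split(igraph::V(sub)$name,
                             igraph::membership(cl)))
    } else {
      out_members <- c(out_members, list(grp))
    }
  }
  out_members <- Filter(function(m) length(m) >= min_size, out_members)
  # deterministic ordering: by smallest member residue
  ord <- order(vapply(out_members, function(m) min(as.integer(m)),
                      numeric(1)))
  out_members <- out_members[ord]
  lapply(seq_along(out_members), function(k) {
    members <- sort(as.integer(out_members[[k]]))
    segs <- if (is.null(segments)) character(0) else
      sort(unique(stats::na.omit(segment_of(segments, members))))
    structure(list(id = paste0("c", k), members = members,
                   segments_touched = segs), class = "Community")
  })
}

#' @export
print.Community <- function(x, ...) {
  cat("Community ", x$id, ": ", length(x$members), " residues",
      if (length(x$segments_touched))
        paste0(" [", paste(x$segments_touched, collapse = ","), "]"),
      "\n", sep = "")
  invisible(x)
}

#' Compare OO-state and IO-state networks
#'
#' Classifies edges as OO-only, IO-only or shared, and matches detected
#' communities between states by member overlap (Jaccard index), listing
#' communities created or disrupted by the state change.
#'
#' @param g_oo,g_io `PSNGraph`s on a common numbering.
#' @param segments Optional segment table for community labels.
#' @param min_size,split_above Community detection parameters.
#' @return List: `edges` (data.frame `i`, `j`, `class`),
#'   `oo_only`, `io_only`, `shared` (edge data.frames),
#'   `oo_communities`, `io_communities` (communities of the state-specific
#'   subgraphs), `matching` (data.frame of cross-state community Jaccard
#'   overlaps).
#' @export
compare_state_networks <- function(g_oo, g_io, segments = NULL,
                                   min_size = 3L, split_above = 30L) {
  koo <- psn_edge_keys(g_oo)
  kio <- psn_edge_keys(g_io)
  oo_only <- g_oo$edges[!koo %in% kio, , drop = FALSE]
  io_only <- g_io$edges[!kio %in% koo, , drop = FALSE]
  shared <- g_oo$edges[koo %in% kio, , drop = FALSE]
  sub_graph <- function(proto, edges) {
    proto$edges <- edges
    proto$nodes <- sort(unique(c(edges$i, edges$j)))
    proto
  }
  oo_comm <- detect_communities(sub_graph(g_oo, oo_only), segments,
                                min_size, split_above)
  io_comm <- detect_communities(sub_graph(g_io, io_only), segments,
                                min_size, split_above)
  matching <- NULL
  for (a in oo_comm) for (b in io_comm) {
    jac <- length(intersect(a$members, b$members)) /
      length(union(a$members, b$members))
    matching <- rbind(matching,
                      data.frame(oo_community = a$id, io_community = b$id,
                                 jaccard = jac))
  }
  edges <- rbind(
    if (nrow(oo_only)) cbind(oo_only[c("i", "j")], class = "OO-only"),
    if (nrow(io_only)) cbind(io_only[c("i", "j")], class = "IO-only"),
    if (nrow(shared)) cbind(shared[c("i", "j")], class = "shared")
  )
  list(edges = edges, oo_only = oo_only, io_only = io_only,
       shared = shared, oo_communities = oo_comm, io_communities = io_comm,
       matching = matching)
}

#' Write a PSN as edge-list TSV and GraphML
#'
#' @param g A `PSNGraph`.
#' @param path_tsv Output TSV path (columns i, j, strength).
#' @param path_graphml Optional GraphML output path.
#' @return Invisibly, the paths written.
#' @export
write_psn <- function(g, path_tsv, path_graphml = NULL) {
  utils::write.table(g$edges, path_tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(path_graphml)) {
    ig <- igraph::graph_from_data_frame(
      data.frame(from = as.character(g$edges$i),
                 to = as.character(g$edges$j),
                 weight = g$edges$strength),
      directed = FALSE)
    igraph::write_graph(ig, path_graphml, format = "graphml")
  }
  invisible(c(path_tsv, path_graphml))
}

#' Adjusted Rand index between two partitions
#'
#' Used to score community recovery against planted ground truth.
#'
#' @param a,b Named membership vectors (names = items); compared over the
#'   union of items, with items absent from a partition placed in their
#'   own singleton class.
#' @return ARI in `[-1, 1]`.
#' @export
adjusted_rand_index <- function(a, b) {
  items <- union(names(a), names(b))
  la <- as.character(a[items])
  lb <- as.character(b[items])
  la[is.na(la)] <- paste0(".singA", seq_len(sum(is.na(la))))
  lb[is.na(lb)] <- paste0(".singB", seq_len(sum(is.na(lb))))
  tab <- table(la, lb)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(items)
  expected <- sum_a * sum_b / comb2(n)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}
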