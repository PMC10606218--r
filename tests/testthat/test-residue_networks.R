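test_that("interaction strength formula and pruning bounds", {
  # two residues in contact with unit capacities -> I = 100
  xyz <- rbind(c(0, 0, 0), c(3.8, 0, 0), c(7.6, 0, 0), c(11.4, 0, 0),
               c(15.2, 0, 0), c(19, 0, 0), c(22.8, 0, 0), c(26.6, 0, 0),
               c(30.4, 0, 0), c(2.5, 2.5, 0))
  m <- structure_model("mini", 1:10, rep("A", 10), xyz)
  norm1 <- setNames(rep(1, 21), c(strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]],
                                  "X"))
  g <- build_psn(m, contact_cutoff = 5, i_min = 3, norm = norm1)
  expect_true(all(g$edges$strength == 100))
  # residue 10 contacts residues 1 and 2 (but |i-j| >= 3 filters residue
  # 1 and 2 from each other along the chain)
  expect_true(all(abs(g$edges$i - g$edges$j) >= 3))
  # pruning bound: i_min above the maximum empties the graph
  g2 <- build_psn(m, contact_cutoff = 5, i_min = 101, norm = norm1)
  expect_equal(nrow(g2$edges), 0L)
  # pruning is monotone: raising i_min never adds edges
  g3 <- build_psn(m, contact_cutoff = 5, i_min = 50, norm = norm1)
  expect_true(all(psn_edge_keys(g3) %in% psn_edge_keys(g)))
})

test_that("planted bundle contacts are recovered in the anchor PSNs", {
  ens <- generate_ensemble(ensemble_config(t_values = c(0, 1)))
  norm <- psn_norm_factors(ens$models[c("OO_anchor", "IO_anchor")])
  g <- build_psn(ens$models$OO_anchor, norm = norm)
  planted <- paste(ens$planted$oo_edges$i, ens$planted$oo_edges$j,
                   sep = "-")
  inter <- g$edges[segment_of(ens$segments, g$edges$i) !=
                     segment_of(ens$segments, g$edges$j), ]
  got <- paste(inter$i, inter$j, sep = "-")
  jac <- length(intersect(got, planted)) / length(union(got, planted))
  expect_gte(jac, 0.8)
})

test_that("consensus semantics: identity, occupancy threshold, intersection", {
  ens <- generate_ensemble(ensemble_config(t_values = c(0, 1)))
  g <- build_psn(ens$models$OO_anchor)
  cons_same <- consensus_network(list(g, g, g))
  expect_equal(cons_same$edges[c("i", "j", "strength")],
               g$edges[c("i", "j", "strength")], ignore_attr = TRUE)
  # an edge present in 1 of 3 graphs is dropped at occupancy 0.5
  g_extra <- g
  g_extra$edges <- rbind(g_extra$edges,
                         data.frame(i = 1L, j = 219L, strength = 50))
  cons <- consensus_network(list(g_extra, g, g), occupancy = 0.5)
  expect_false("1-219" %in% psn_edge_keys(cons))
  # occupancy 1.0 equals the edge-set intersection
  g_less <- g
  g_less$edges <- g$edges[-1, ]
  cons_int <- consensus_network(list(g, g_less), occupancy = 1.0)
  expect_setequal(psn_edge_keys(cons_int), psn_edge_keys(g_less))
})

test_that("consensus over noisy state replicates keeps planted edges only", {
  cfg <- ensemble_config(t_values = rep(0, 8), noise_sigma = 0.2,
                         seed = 21)
  ens <- generate_ensemble(cfg)
  reps <- ens$models[grep("^model_", names(ens$models))]
  # distinct noisy replicates of the OO state
  norm <- psn_norm_factors(ens$models[c("OO_anchor", "IO_anchor")])
  graphs <- lapply(reps, build_psn, norm = norm)
  cons <- consensus_network(graphs, occupancy = 0.5)
  seg <- function(r) segment_of(ens$segments, r)
  inter <- cons$edges[seg(cons$edges$i) != seg(cons$edges$j), ]
  got <- paste(inter$i, inter$j, sep = "-")
  planted_oo <- paste(ens$planted$oo_edges$i, ens$planted$oo_edges$j,
                      sep = "-")
  planted_io <- paste(ens$planted$io_edges$i, ens$planted$io_edges$j,
                      sep = "-")
  jac <- length(intersect(got, planted_oo)) /
    length(union(got, planted_oo))
  expect_gte(jac, 0.8)
  expect_length(intersect(got, planted_io), 0L)
})

test_that("two disjoint triangles give two communities of size 3", {
  edges <- data.frame(i = c(1, 1, 4, 10, 10, 13),
                      j = c(4, 7, 7, 13, 16, 16),
                      strength = 50)
  g <- structure(list(nodes = unique(c(edges$i, edges$j)), edges = edges,
                      i_min = 3, contact_cutoff = 5, norm = NULL,
                      model_id = "toy"), class = "PSNGraph")
  comms <- detect_communities(g)
  expect_length(comms, 2L)
  expect_equal(sort(comms[[1]]$members), c(1, 4, 7))
  expect_equal(sort(comms[[2]]$members), c(10, 13, 16))
  # empty graph -> empty list
  g$edges <- edges[0, ]
  expect_length(detect_communities(g), 0L)
})

test_that("planted state-specific communities are recovered exactly at sigma 0", {
  ens <- generate_ensemble(ensemble_config(t_values = c(0, 1)))
  norm <- psn_norm_factors(ens$models[c("OO_anchor", "IO_anchor")])
  g_oo <- build_psn(ens$models$OO_anchor, norm = norm)
  g_io <- build_psn(ens$models$IO_anchor, norm = norm)
  cmp <- compare_state_networks(g_oo, g_io, segments = ens$segments)
  to_part <- function(comms) {
    out <- integer(0)
    for (co in comms)
      out <- c(out, setNames(rep(match(co$id, vapply(comms, `[[`,
                                                     character(1), "id")),
                                 length(co$members)),
                             co$members))
    out
  }
  expect_equal(adjusted_rand_index(to_part(cmp$oo_communities),
                                   ens$planted$oo_partition), 1)
  expect_equal(adjusted_rand_index(to_part(cmp$io_communities),
                                   ens$planted$io_partition), 1)
  # the community segment labels reproduce the planted helix triples
  oo_segs <- sort(unique(unlist(lapply(cmp$oo_communities,
                                       `[[`, "segments_touched"))))
  io_segs <- sort(unique(unlist(lapply(cmp$io_communities,
                                       `[[`, "segments_touched"))))
  expect_equal(oo_segs, sort(ens$cfg$oo_community))
  expect_equal(io_segs, sort(ens$cfg$io_community))
})

test_that("state comparison edge classes: self gives shared, empty gives OO-only", {
  ens <- generate_ensemble(ensemble_config(t_values = c(0, 1)))
  g <- build_psn(ens$models$OO_anchor)
  cmp_self <- compare_state_networks(g, g)
  expect_equal(nrow(cmp_self$oo_only), 0L)
  expect_equal(nrow(cmp_self$io_only), 0L)
  expect_equal(nrow(cmp_self$shared), nrow(g$edges))
  g_empty <- g
  g_empty$edges <- g$edges[0, ]
  cmp_empty <- compare_state_networks(g, g_empty)
  expect_equal(nrow(cmp_empty$oo_only), nrow(g$edges))
  expect_equal(nrow(cmp_empty$shared), 0L)
})

test_that("adjusted Rand index: perfect, permuted labels, random baseline", {
  a <- setNames(c(1, 1, 1, 2, 2, 2), letters[1:6])
  expect_equal(adjusted_rand_index(a, a), 1)
  b <- setNames(c(9, 9, 9, 4, 4, 4), letters[1:6])
  expect_equal(adjusted_rand_index(a, b), 1)
  d <- setNames(c(1, 2, 1, 2, 1, 2), letters[1:6])
  expect_lt(adjusted_rand_index(a, d), 0.5)
})
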