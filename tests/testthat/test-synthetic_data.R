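test_that("anchors: t = 0 equals anchor A; RMSD grows strictly with t", {
  ens <- generate_ensemble(ensemble_config())
  expect_equal(ens$models[["model_t0.00"]]$xyz, ens$models$OO_anchor$xyz)
  ts <- seq(0, 1, by = 0.1)
  rmsds <- vapply(sprintf("model_t%.2f", ts), function(id)
    kabsch_superpose(ens$models$OO_anchor$xyz, ens$models[[id]]$xyz)$rmsd,
    numeric(1))
  expect_true(all(diff(rmsds) > 0))
})

test_that("generation is bit-reproducible given the seed", {
  a <- generate_ensemble(ensemble_config(noise_sigma = 0.4, seed = 17))
  b <- generate_ensemble(ensemble_config(noise_sigma = 0.4, seed = 17))
  expect_identical(a$models, b$models)
  expect_identical(a$truth, b$truth)
  c_ <- generate_ensemble(ensemble_config(noise_sigma = 0.4, seed = 18))
  expect_false(identical(a$models, c_$models))
})

test_that("ground-truth states follow the documented t bands", {
  ens <- generate_ensemble(ensemble_config(t_values = c(0.1, 0.4, 0.9)))
  st <- setNames(ens$truth$state, ens$truth$model_id)
  expect_equal(unname(st["model_t0.10"]), "OO")
  expect_equal(unname(st["model_t0.40"]), "intermediate")
  expect_equal(unname(st["model_t0.90"]), "IO")
})

test_that("the generator model sequence equals the template sequence", {
  ens <- generate_ensemble(ensemble_config(t_values = 0.5))
  expect_equal(sequence_of(ens$models[["model_t0.50"]]),
               ens$template_sequence)
  expect_equal(nchar(ens$template_sequence),
               ens$cfg$n_helices * ens$cfg$helix_length)
})

test_that("planted contacts are exclusive to their state", {
  ens <- generate_ensemble(ensemble_config(t_values = c(0, 1)))
  expect_gt(nrow(ens$planted$oo_edges), 0L)
  expect_gt(nrow(ens$planted$io_edges), 0L)
  key <- function(df) paste(df$i, df$j, sep = "-")
  expect_length(intersect(key(ens$planted$oo_edges),
                          key(ens$planted$io_edges)), 0L)
  # config validation
  expect_error(ensemble_config(mobile = c("h1", "h99")), "mobile subset")
  expect_error(ensemble_config(t_values = c(-0.1, 0.5)), "\\[0, 1\\]")
})

test_that("response table semantics: unlisted silent, combos override", {
  tb <- response_table(
    singles = list(YN = list(t = 0), SUP = list(t = 1)),
    combos = setNames(list(list(t = 0.1)), combo_key(c("YN", "SUP"))),
    native_t = 1)
  expect_equal(resolve_response("unknown", tb)$t, 1)
  expect_equal(resolve_response("YN", tb)$t, 0)
  expect_equal(resolve_response(c("YN", "SUP"), tb)$t, 0.1)
  # default combination rule: the most displacing single dominates
  expect_equal(resolve_response(c("YN", "unknown"), tb)$t, 0)
  expect_error(response_table(singles = list(bad = list(t = 2))),
               "\\[0, 1\\]")
})

test_that("simulated mutants land on the requested coordinate", {
  ens <- generate_ensemble(ensemble_config(t_values = c(0, 1)))
  tb <- response_table(singles = list(SW = list(t = 0)), native_t = 1)
  sw <- simulate_mutant_response(ens, "SW", tb, sigma = 0)
  expect_equal(sw$xyz, ens$models$OO_anchor$xyz, tolerance = 1e-12)
  wt <- simulate_mutant_response(ens, "unlisted", tb, sigma = 0)
  expect_equal(wt$xyz, ens$models$IO_anchor$xyz, tolerance = 1e-12)
  # per-helix displacement moves exactly that helix
  tb2 <- response_table(singles = list(
    P = list(t = 1, helix_shift = c(h5 = 4))), native_t = 1)
  pm <- simulate_mutant_response(ens, "P", tb2, sigma = 0)
  d <- sqrt(rowSums((pm$xyz - ens$models$IO_anchor$xyz)^2))
  hid <- rep(ens$cfg$helices, each = ens$cfg$helix_length)
  expect_equal(
    as.numeric(tapply(d, hid, max)[setdiff(ens$cfg$helices, "h5")]),
    rep(0, 10), tolerance = 1e-12)
  expect_equal(as.numeric(tapply(d, hid, min)["h5"]), 4,
               tolerance = 1e-9)
})

test_that("grouped MSA generator: determinism, planting, disjointness", {
  g1 <- generate_grouped_msa(planted_type_ii = c(3L, 9L), seed = 4)
  g2 <- generate_grouped_msa(planted_type_ii = c(3L, 9L), seed = 4)
  expect_identical(g1$msa$seqs, g2$msa$seqs)
  expect_error(generate_grouped_msa(planted_type_ii = 1:3,
                                    planted_selective = 2:4), "disjoint")
  expect_error(generate_grouped_msa(planted_type_ii = 9999L),
               "out of range")
  # no planted columns -> no type-ii shifts at threshold 0.9
  g0 <- generate_grouped_msa(seed = 6)
  sh <- type_ii_shifts(g0$msa, c("g1", "g2"))
  expect_equal(sum(sh$type == "ii"), 0L)
  # planted conservation is the exact-count convention
  gsel <- generate_grouped_msa(planted_selective = 10L, seed = 8)
  m <- do.call(rbind, strsplit(gsel$msa$seqs, ""))
  grp <- gsel$truth$selective$group[1]
  col <- m[gsel$msa$groups == grp, 10]
  expect_equal(max(table(col)), 10)
})
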