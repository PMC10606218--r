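ens_noiseless <- generate_ensemble(ensemble_config())

test_that("elastic similarity: self-maximum, symmetry, direct summation", {
  a <- ens_noiseless$models$OO_anchor
  b <- ens_noiseless$models$IO_anchor
  prm <- elastic_params()
  saa <- elastic_similarity(a, a, params = prm)
  sab <- elastic_similarity(a, b, params = prm)
  # self-comparison attains theta * (sum of envelope weights + n)
  d <- as.matrix(dist(a$xyz)); ut <- upper.tri(d)
  expected_self <- prm$theta * (sum(exp(-(d[ut] / prm$envelope_scale)^2)) +
                                  n_residues(a))
  expect_equal(saa, expected_self, tolerance = 1e-9)
  expect_gt(saa, sab)
  expect_equal(sab, elastic_similarity(b, a, params = prm),
               tolerance = 1e-9)
})

test_that("elastic similarity equals hand summation on a 4-residue toy", {
  xyz <- rbind(c(0, 0, 0), c(3.8, 0, 0), c(7.6, 0, 0), c(11.4, 0, 0))
  a <- structure_model("a", 1:4, rep("A", 4), xyz)
  xyz_b <- xyz
  xyz_b[4, 1] <- 12.4  # perturb one distance set by 1 A
  b <- structure_model("b", 1:4, rep("A", 4), xyz_b)
  prm <- elastic_params(theta = 0.2, envelope_scale = 20)
  # direct summation over all 6 pairs + 4 theta terms
  da <- as.matrix(dist(xyz)); db <- as.matrix(dist(xyz_b))
  acc <- 0
  for (i in 1:3) for (j in (i + 1):4) {
    dstar <- (da[i, j] + db[i, j]) / 2
    acc <- acc + (0.2 - abs(da[i, j] - db[i, j]) / dstar) *
      exp(-(dstar / 20)^2)
  }
  expect_equal(elastic_similarity(a, b, params = prm), acc + 4 * 0.2,
               tolerance = 1e-12)
  expect_error(elastic_similarity(a, b, map = structure(
    list(pairs = cbind(1:2, 1:2), identity = 1), class = "ResidueMap")),
    "3 mapped")
})

test_that("all-against-all similarity is monotone in the planted coordinate", {
  ens <- generate_ensemble(ensemble_config(t_values = c(0, 0.5, 1)))
  cm <- aaa_matrix(ens$models, "OO_anchor", "IO_anchor")
  s <- cm$similarity
  expect_equal(s, t(s), tolerance = 1e-9)
  expect_gt(s["model_t0.00", "model_t0.50"], s["model_t0.00", "model_t1.00"])
  # diagonal maximal per row
  expect_true(all(diag(s) >= apply(s, 1, max) - 1e-9))
  # identical models score identically against the rest
  expect_equal(s["OO_anchor", "model_t1.00"], s["model_t0.00", "model_t1.00"],
               tolerance = 1e-9)
})

test_that("embedding separates planted clusters and orders the series", {
  cm <- cartography(ens_noiseless$models, "OO_anchor", "IO_anchor")
  emb <- cm$embedding
  tr <- ens_noiseless$truth
  tv <- tr$t[match(rownames(emb), tr$model_id)]
  expect_gte(abs(cor(emb[, 1], tv, method = "spearman")), 0.99)
  # rank agreement with classical MDS on the dissimilarity transform
  diss <- max(cm$similarity) - cm$similarity
  diag(diss) <- 0
  mds <- cmdscale(as.dist(diss), k = 2)
  expect_gte(abs(cor(rank(mds[, 1]), rank(emb[, 1]))), 0.95)
  # two tight clusters: OO-band vs IO-band silhouette on axis 1
  oo <- tr$model_id[tr$t <= 0.1]
  io <- tr$model_id[tr$t >= 0.9]
  sil <- vapply(c(oo, io), function(id) {
    own <- if (id %in% oo) oo else io
    oth <- if (id %in% oo) io else oo
    a_ <- mean(abs(emb[setdiff(own, id), 1] - emb[id, 1]))
    b_ <- mean(abs(emb[oth, 1] - emb[id, 1]))
    (b_ - a_) / max(a_, b_)
  }, numeric(1))
  expect_gt(mean(sil), 0.8)
})

test_that("embedding is reproducible up to canonicalized sign", {
  cm1 <- correspondence_embed(aaa_matrix(ens_noiseless$models,
                                         "OO_anchor", "IO_anchor"))
  cm2 <- correspondence_embed(aaa_matrix(ens_noiseless$models,
                                         "OO_anchor", "IO_anchor"))
  expect_equal(cm1$embedding, cm2$embedding)
  expect_true(all(apply(abs(cm1$embedding), 2, max) ==
                    apply(cm1$embedding, 2, max)))
})

test_that("state assignment: anchors correct, swap antisymmetry, margins in [-1,1]", {
  cm <- assign_states(aaa_matrix(ens_noiseless$models,
                                 "OO_anchor", "IO_anchor"), delta = 1 / 3)
  st <- setNames(cm$state_calls$state, cm$state_calls$model_id)
  expect_equal(unname(st["OO_anchor"]), "OO")
  expect_equal(unname(st["IO_anchor"]), "IO")
  expect_equal(unname(st["model_t0.50"]), "intermediate")
  expect_true(all(abs(cm$state_calls$margin) <= 1 + 1e-12))
  # swapping the anchors swaps OO and IO calls
  swapped <- assign_states(aaa_matrix(ens_noiseless$models,
                                      "IO_anchor", "OO_anchor"),
                           delta = 1 / 3)
  st2 <- setNames(swapped$state_calls$state, swapped$state_calls$model_id)
  expect_equal(unname(st2["OO_anchor"]), "IO")
  expect_equal(unname(st2["IO_anchor"]), "OO")
  flip <- c(OO = "IO", IO = "OO", intermediate = "intermediate")
  expect_equal(unname(flip[st]), unname(st2[names(st)]))
})

test_that("transition order starts at OO, ends at IO, follows planted t", {
  cm <- cartography(ens_noiseless$models, "OO_anchor", "IO_anchor")
  ord <- cm$transition_order
  expect_equal(ord[1], "OO_anchor")
  expect_true(ord[length(ord)] %in% c("IO_anchor", "model_t1.00"))
  tr <- ens_noiseless$truth
  tv <- tr$t[match(ord, tr$model_id)]
  expect_true(all(diff(tv) >= 0))
})

test_that("anchor and pool-size validation", {
  mods <- ens_noiseless$models[1:3]
  expect_error(aaa_matrix(mods, "nope", "IO_anchor"), "anchors")
  expect_error(aaa_matrix(mods[1:2], "OO_anchor", "IO_anchor"),
               "at least 3")
})
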