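test_that("pattern compilation: tokens, gaps, round trip, errors", {
  p <- compile_pattern("G[AS]G")
  expect_length(p$tokens, 3L)
  expect_equal(render_pattern(p), "G[AS]G")
  g <- compile_pattern("x(2,50)")
  expect_equal(g$tokens[[1]]$min, 2L)
  expect_equal(g$tokens[[1]]$max, 50L)
  expect_error(compile_pattern("x(5,"), "unterminated")
  expect_error(compile_pattern("G[ASG"), "unbalanced")
  expect_error(compile_pattern("x(7,3)"), "minimum exceeds")
  # the shipped MCg1 pattern round-trips
  mp <- compile_pattern(mcg1_pattern())
  expect_equal(render_pattern(mp), mcg1_pattern())
  # the extdata copy equals the in-code pattern
  f <- system.file("extdata", "mcg1_selective_pattern.txt",
                   package = "conformoscope")
  expect_equal(readLines(f), mcg1_pattern())
})

test_that("basic matching with spans", {
  r <- match_pattern("G[AS]G", "TGAGT")
  expect_true(r$match)
  expect_equal(c(r$start, r$end), c(2L, 4L))
  expect_false(match_pattern("G[AS]G", "GTTG")$match)
  # gap stretch
  r2 <- match_pattern("Ax(2,3)C", "KKAGGCK")
  expect_true(r2$match)
  expect_equal(c(r2$start, r2$end), c(3L, 6L))
  expect_false(match_pattern("Ax(2,3)C", "KKAGC")$match)
})

test_that("matcher agrees with a regex-engine oracle on random sequences", {
  mp <- compile_pattern(mcg1_pattern())
  rx <- pattern_to_regex(mcg1_pattern())
  small <- compile_pattern("G[AS]Gx(2,8)[LV]AE")
  rx_small <- pattern_to_regex("G[AS]Gx(2,8)[LV]AE")
  set.seed(42)
  n_agree <- 0L
  for (i in 1:250) {
    s <- random_aa_seq(sample(50:700, 1))
    expect_equal(match_pattern(mp, s)$match, grepl(rx, s, perl = TRUE))
    expect_equal(match_pattern(small, s)$match,
                 grepl(rx_small, s, perl = TRUE))
    n_agree <- n_agree + 1L
  }
  expect_equal(n_agree, 250L)
})

test_that("constructive expansions of the MCg1 pattern match; violations fail", {
  mp <- compile_pattern(mcg1_pattern())
  rx <- pattern_to_regex(mcg1_pattern())
  for (sd in 1:10) {
    e <- expand_pattern_random(mp, seed = sd)
    flanked <- paste0(random_aa_seq(sample(0:30, 1)), e,
                      random_aa_seq(sample(0:30, 1)))
    expect_true(match_pattern(mp, flanked)$match)
    expect_true(grepl(rx, flanked, perl = TRUE))
    # violate the first literal class (G -> W cannot satisfy any class
    # at that token)
    broken <- e
    substr(broken, 1, 1) <- "W"
    expect_equal(match_pattern(mp, broken)$match,
                 grepl(rx, broken, perl = TRUE))
  }
})

test_that("type-ii and type-i rate shifts on hand-built columns", {
  seqs <- c("AAG", "AAG", "AAG", "AAG",   # group 1: A A G
            "YAC", "YAC", "YAC", "YAT")   # group 2: Y A mixed
  msa <- grouped_msa(seqs, rep(c("g1", "g2"), each = 4))
  sh <- type_ii_shifts(msa, c("g1", "g2"), conservation_threshold = 0.9)
  expect_equal(sh$type[sh$column == 1], "ii")     # A vs Y, both conserved
  expect_false(2 %in% sh$column)                  # same residue: no shift
  expect_equal(sh$type[sh$column == 3], "i")      # conserved in g1 only
  # relabeling the groups preserves the shift count
  msa_swap <- grouped_msa(seqs, rep(c("g2", "g1"), each = 4))
  sh2 <- type_ii_shifts(msa_swap, c("g1", "g2"))
  expect_equal(nrow(sh2), nrow(sh))
  expect_error(type_ii_shifts(msa, c("g1", "gX")), "absent")
})

test_that("planted type-ii columns are recovered without false positives", {
  cols <- c(5L, 50L, 120L, 200L, 301L, 390L)
  g <- generate_grouped_msa(planted_type_ii = cols, seed = 31)
  sh <- type_ii_shifts(g$msa, c("g1", "g2"))
  expect_setequal(sh$column[sh$type == "ii"], cols)
})

test_that("group-specific site scoring: trivial columns behave", {
  # identical profiles across groups -> zero divergence, not selected;
  # disjoint conserved residues -> extreme scores in selecting direction
  seqs <- c(paste0("AK", strrep("L", 8)), paste0("AK", strrep("L", 8)),
            paste0("AK", strrep("L", 8)), paste0("AE", strrep("L", 8)),
            paste0("AE", strrep("L", 8)), paste0("AE", strrep("L", 8)))
  msa <- grouped_msa(seqs, rep(c("g1", "g2"), each = 3))
  sc <- group_specific_sites(msa, n_subsamples = 20, seed = 2)
  expect_lt(sc$sh_divergence[1], 0.05)
  expect_false(sc$selected[1])
  # the disjoint column attains the maximal divergence in this
  # alignment (pseudocounts cap the absolute value for small groups)
  expect_equal(which.max(sc$sh_divergence), 2L)
  expect_gt(sc$sh_divergence[2], 5 * max(sc$sh_divergence[1], 0.01))
  expect_lt(sc$z_score[2], sc$z_score[1])
  expect_gt(sc$z_weight[2], sc$z_weight[1])
  expect_error(group_specific_sites(
    grouped_msa(seqs[c(1, 4)], c("g1", "g2"))), "at least 3 sequences")
})

test_that("planted selective columns are recovered at the z thresholds", {
  set.seed(77)
  cols <- sort(sample(400, 45))
  g <- generate_grouped_msa(planted_selective = cols, seed = 13)
  sc <- group_specific_sites(g$msa, n_subsamples = 100, seed = 14)
  hit <- sc$column[sc$selected]
  precision <- mean(hit %in% cols)
  recall <- mean(cols %in% hit)
  expect_gte(precision, 0.9)
  expect_gte(recall, 0.9)
  # determinism given the seed
  sc2 <- group_specific_sites(g$msa, n_subsamples = 100, seed = 14)
  expect_identical(sc, sc2)
})

test_that("gap-majority columns are excluded from standardization", {
  seqs <- c("A-KLM", "A-KLM", "A-KLM", "Y-KLM", "Y-KLM", "Y-KLM")
  msa <- grouped_msa(seqs, rep(c("g1", "g2"), each = 3))
  sc <- group_specific_sites(msa, n_subsamples = 10, seed = 3)
  expect_true(is.na(sc$z_score[2]))
  expect_false(sc$selected[2])
})

test_that("clade consensus: single sequence, majority and gap majority", {
  msa <- grouped_msa(c("AAG", "AAG", "GA-"), c("g1", "g1", "g2"))
  c1 <- clade_consensus(msa, "g1")
  expect_equal(c1$consensus, c("A", "A", "G"))
  c2 <- clade_consensus(msa, "g2")
  expect_equal(c2$consensus, c("G", "A", "-"))
  msa2 <- grouped_msa(c("AAG", "AGG", "AG-"), rep("g1", 3))
  c3 <- clade_consensus(msa2, "g1")
  expect_equal(c3$consensus[2], "G")
  expect_equal(c3$frequency[2], round(2 / 3, 4))
})
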