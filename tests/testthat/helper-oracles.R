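# Independent oracles and small fixture builders used across the suite.
# Everything here is deliberately naive (enumeration, grid search, regex
# translation) and independent of the package's implementation paths.

# ---- brute-force global alignment oracle (tiny sequences) -------------
# Enumerates all global alignments of a and b under BLOSUM62 with affine
# gap cost open + k * extend per gap run (end gaps penalized), returning
# the maximum score. Only feasible for sequences of length <= ~6.
oracle_alignment_score <- function(a, b, open = 11, extend = 1) {
  data_env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = data_env)
  bl <- data_env$BLOSUM62
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  best <- -Inf
  # state: (i consumed of a, j consumed of b, last move) with gap runs
  # scored on close; recursion over moves M (match), A (gap in b), B
  # (gap in a)
  rec <- function(i, j, last, score) {
    if (i == length(av) && j == length(bv)) {
      best <<- max(best, score)
      return(invisible())
    }
    if (i < length(av) && j < length(bv)) {
      rec(i + 1, j + 1, "M", score + bl[av[i + 1], bv[j + 1]])
    }
    if (i < length(av)) {
      pen <- if (last == "A") extend else open + extend
      rec(i + 1, j, "A", score - pen)
    }
    if (j < length(bv)) {
      pen <- if (last == "B") extend else open + extend
      rec(i, j + 1, "B", score - pen)
    }
  }
  rec(0, 0, "none", 0)
  best
}

# Score the alignment implied by a ResidueMap under the same convention.
score_of_map <- function(map, a, b, open = 11, extend = 1) {
  data_env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = data_env)
  bl <- data_env$BLOSUM62
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  p <- map$pairs
  score <- sum(bl[cbind(av[p[, 1]], bv[p[, 2]])])
  gap_cost <- function(len) if (len > 0) open + extend * len else 0
  # unpaired stretches between/around pairs form separate gap runs per
  # sequence
  bounds_a <- c(0, p[, 1], length(av) + 1)
  bounds_b <- c(0, p[, 2], length(bv) + 1)
  for (k in seq_len(length(bounds_a) - 1)) {
    score <- score - gap_cost(bounds_a[k + 1] - bounds_a[k] - 1)
    score <- score - gap_cost(bounds_b[k + 1] - bounds_b[k] - 1)
  }
  score
}

# ---- rotation-grid superposition oracle -------------------------------
# Hierarchical grid search over proper rotations (ZYZ Euler angles),
# optimal translation by centroid matching. Accurate to ~1e-6 A RMSD on
# small point sets; completely independent of the SVD route.
oracle_grid_rmsd <- function(a, b) {
  a0 <- sweep(a, 2, colMeans(a))
  b0 <- sweep(b, 2, colMeans(b))
  rot_zyz <- function(al, be, ga) {
    rz <- function(t) matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0,
                               0, 0, 1), 3, 3)
    ry <- function(t) matrix(c(cos(t), 0, -sin(t), 0, 1, 0,
                               sin(t), 0, cos(t)), 3, 3)
    rz(al) %*% ry(be) %*% rz(ga)
  }
  rmsd_rot <- function(r) sqrt(mean(rowSums((b0 %*% t(r) - a0)^2)))
  rodrigues <- function(v) {
    th <- sqrt(sum(v^2))
    if (th < 1e-12) return(diag(3))
    k <- v / th
    kx <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0),
                 3, 3, byrow = TRUE)
    diag(3) + sin(th) * kx + (1 - cos(th)) * kx %*% kx
  }
  # coarse pass (15 degree steps over all of SO(3), Euler ZYZ)
  grid <- expand.grid(al = seq(0, 2 * pi, length.out = 25)[-25],
                      be = seq(0, pi, length.out = 13),
                      ga = seq(0, 2 * pi, length.out = 25)[-25])
  vals <- mapply(function(al, be, ga) rmsd_rot(rot_zyz(al, be, ga)),
                 grid$al, grid$be, grid$ga)
  i0 <- which.min(vals)
  best_r <- rot_zyz(grid$al[i0], grid$be[i0], grid$ga[i0])
  best_v <- rmsd_rot(best_r)
  # local refinement in the rotation tangent space (well-conditioned
  # everywhere, unlike Euler angles near the gimbal axis)
  step <- pi / 12
  offs3 <- function(st) {
    g <- expand.grid(x = c(-st, 0, st), y = c(-st, 0, st),
                     z = c(-st, 0, st))
    g[!(g$x == 0 & g$y == 0 & g$z == 0), ]
  }
  for (lvl in 1:26) {
    g2 <- offs3(step)
    improved <- FALSE
    for (k in seq_len(nrow(g2))) {
      r2 <- rodrigues(as.numeric(g2[k, ])) %*% best_r
      v2 <- rmsd_rot(r2)
      if (v2 < best_v) { best_v <- v2; best_r <- r2; improved <- TRUE }
    }
    if (!improved) step <- step / 2
    if (step < 1e-6) break
  }
  best_v
}

# ---- regex-engine oracle for PROSITE-style patterns -------------------
# Independent textual translation of the pattern grammar to a PCRE.
pattern_to_regex <- function(text) {
  rx <- gsub("x\\(([0-9]+),([0-9]+)\\)", ".{\\1,\\2}", text)
  rx <- gsub("x\\(([0-9]+)\\)", ".{\\1}", rx)
  gsub("x", ".", rx, fixed = TRUE)
}

# Random expansion of a pattern (each class: random member; each gap:
# random length in range, random residues).
expand_pattern_random <- function(p, seed) {
  withr_seed <- function(code) code
  set.seed(seed)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  paste(vapply(p$tokens, function(tk) {
    if (tk$type == "gap") {
      len <- sample(tk$min:tk$max, 1)
      paste(sample(aa, len, replace = TRUE), collapse = "")
    } else {
      sample(tk$set, 1)
    }
  }, character(1)), collapse = "")
}

random_aa_seq <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n,
               replace = TRUE), collapse = "")
}

# ---- small structure fixtures -----------------------------------------
toy_model <- function(id = "toy", n = 5, seed = 1) {
  set.seed(seed)
  structure_model(id, seq_len(n),
                  sample(c("A", "C", "D", "E", "G"), n, replace = TRUE),
                  matrix(rnorm(3 * n, sd = 5), n, 3))
}

rigid_move <- function(xyz, angle = pi / 5, axis = c(0, 0, 1),
                       shift = c(3, -2, 7)) {
  axis <- axis / sqrt(sum(axis^2))
  c_ <- cos(angle); s_ <- sin(angle)
  k <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  r <- diag(3) + s_ * k + (1 - c_) * k %*% k
  sweep(xyz %*% t(r), 2, shift, `+`)
}

write_mini_pdb <- function(path, resnames, coords, bfac = NULL) {
  n <- length(resnames)
  if (is.null(bfac)) bfac <- rep(0, n)
  lines <- sprintf(
    "ATOM  %5d  CA  %3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
    seq_len(n), resnames, seq_len(n),
    coords[, 1], coords[, 2], coords[, 3], 1, bfac)
  writeLines(c(lines, "END"), path)
  path
}
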