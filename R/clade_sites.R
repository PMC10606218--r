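# Sequence-level clade analytics: PROSITE-style pattern compilation and
# matching, type-ii evolutionary rate-shift detection, and group-specific
# site scoring (Sequence-Harmony / Multi-Relief style) with z thresholds.

#' The MCg1-selective sequence pattern
#'
#' The diagnostic PROSITE-style pattern for the MCg1 clade of bacterial
#' Slc11 (MntH C) carriers, used for local pattern matching in place of a
#' remote PHI-BLAST search. Also shipped as
#' `inst/extdata/mcg1_selective_pattern.txt`.
#'
#' @return The pattern string.
#' @export
mcg1_pattern <- function() {
  paste0(
    "G[ASP]G[LAVSTIM][LM][VI]AVGY[MIV]DPGNWAT[DEASG]x(30,100)",
    "[IVL]A[CT][DA][LV]AE[VIL][IVLA]Gx(5,30)",
    "[GAVCSL][TAS][LFYIVC][AVGILST][MLVI]x(50,125)",
    "[IVM][LVI]GAT[LVI]MPHN[LI][YF]L[HQ][SGA]x(5,40)",
    "[FMLT][LVATIC][VILA]N[SAGL][ASG]x(2,50)",
    "[ACS]G[QLM][SN][SA][TA][VLI]T[GAS]")
}

#' Compile a PROSITE-style pattern
#'
#' Grammar: literal residues (`G`), residue classes (`[ASP]`), and gaps
#' `x` / `x(m)` / `x(m,n)` matching any residue. Rendering the compiled
#' tokens reproduces the source text.
#'
#' @param text Pattern string.
#' @return A list of class `SequencePattern` with `tokens` and
#'   `source_text`.
#' @export
compile_pattern <- function(text) {
  chars <- strsplit(text, "")[[1]]
  tokens <- list()
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) stop("unbalanced '[' at position ", i)
      set <- chars[(i + 1):(j - 1)]
      if (!length(set) || !all(set %in% LETTERS))
        stop("invalid residue class at position ", i)
      tokens[[length(tokens) + 1L]] <- list(type = "class", set = set)
      i <- j + 1L
    } else if (ch == "x") {
      if (i < n && chars[i + 1] == "(") {
        j <- i + 1L
        while (j <= n && chars[j] != ")") j <- j + 1L
        if (j > n) stop("unterminated gap length at position ", i)
        body <- paste(chars[(i + 2):(j - 1)], collapse = "")
        parts <- strsplit(body, ",", fixed = TRUE)[[1]]
        if (!length(parts) || length(parts) > 2L ||
            !all(grepl("^[0-9]+$", parts)))
          stop("malformed gap specification 'x(", body, ")'")
        mn <- as.integer(parts[1])
        mx <- if (length(parts) == 2L) as.integer(parts[2]) else mn
        if (mn > mx) stop("gap minimum exceeds maximum in 'x(", body, ")'")
        tokens[[length(tokens) + 1L]] <- list(type = "gap", min = mn,
                                              max = mx)
        i <- j + 1L
      } else {
        tokens[[length(tokens) + 1L]] <- list(type = "gap", min = 1L,
                                              max = 1L)
        i <- i + 1L
      }
    } else if (ch %in% LETTERS) {
      tokens[[length(tokens) + 1L]] <- list(type = "class", set = ch)
      i <- i + 1L
    } else if (grepl("^\\s$", ch)) {
      i <- i + 1L
    } else {
      stop("unexpected character '", ch, "' at position ", i)
    }
  }
  if (!length(tokens)) stop("empty pattern")
  structure(list(tokens = tokens, source_text = text),
            class = "SequencePattern")
}

#' Render a compiled pattern back to text
#' @param p A [compile_pattern()] result.
#' @return Pattern string (equal to the source modulo whitespace).
#' @export
render_pattern <- function(p) {
  paste(vapply(p$tokens, function(tk) {
    if (tk$type == "gap") {
      if (tk$min == 1L && tk$max == 1L) "x"
      else if (tk$min == tk$max) sprintf("x(%d)", tk$min)
      else sprintf("x(%d,%d)", tk$min, tk$max)
    } else if (length(tk$set) == 1L) tk$set
    else paste0("[", paste(tk$set, collapse = ""), "]")
  }, character(1)), collapse = "")
}

#' @export
print.SequencePattern <- function(x, ...) {
  cat("SequencePattern: ", length(x$tokens), " tokens: ",
      substr(render_pattern(x), 1, 60), "...\n", sep = "")
  invisible(x)
}

#' Match a compiled pattern against a sequence
#'
#' Finds whether any substring of `seq` matches the token list (gap
#' ranges explored exhaustively via dynamic programming, so no
#' backtracking blow-up). On success, the first match (smallest start,
#' then shortest) is reconstructed and the spans of all non-gap tokens
#' are reported.
#'
#' @param p A [compile_pattern()] result (or pattern text).
#' @param seq Sequence string.
#' @return List: `match` (logical), `start`, `end` (1-based, NA if no
#'   match), `spans` (data.frame `token`, `start`, `end` for class
#'   tokens of the first match).
#' @export
match_pattern <- function(p, seq) {
  if (is.character(p)) p <- compile_pattern(p)
  s <- strsplit(toupper(seq), "")[[1]]
  L <- length(s)
  K <- length(p$tokens)
  # feas[k, pos]: can tokens k..K match starting at sequence offset pos?
  # pos ranges 1..L+1 (L+1 = empty remainder)
  feas <- matrix(FALSE, K + 1L, L + 2L)
  feas[K + 1L, seq_len(L + 1L)] <- TRUE
  for (k in K:1) {
    tk <- p$tokens[[k]]
    nxt <- feas[k + 1L, ]
    row <- rep(FALSE, L + 2L)
    if (tk$type == "class") {
      pos <- seq_len(L)
      row[pos] <- s %in% tk$set & nxt[pos + 1L]
    } else {
      cnt <- cumsum(nxt[seq_len(L + 1L)])
      pos <- seq_len(L + 1L)
      lo <- pos + tk$min
      hi <- pmin(pos + tk$max, L + 1L)
      ok <- lo <= hi
      lo2 <- lo[ok]; hi2 <- hi[ok]
      row[pos[ok]] <- (cnt[hi2] - ifelse(lo2 > 1L, cnt[lo2 - 1L], 0)) > 0
    }
    feas[k, ] <- row
  }
  starts <- which(feas[1L, seq_len(L)])
  if (!length(starts)) {
    return(list(match = FALSE, start = NA_integer_, end = NA_integer_,
                spans = data.frame(token = integer(0), start = integer(0),
                                   end = integer(0))))
  }
  # reconstruct the first match greedily (shortest gaps first)
  pos <- starts[1L]
  spans <- NULL
  for (k in seq_len(K)) {
    tk <- p$tokens[[k]]
    if (tk$type == "class") {
      spans <- rbind(spans, data.frame(token = k, start = pos, end = pos))
      pos <- pos + 1L
    } else {
      g <- tk$min
      while (g <= tk$max && !(pos + g <= L + 1L && feas[k + 1L, pos + g]))
        g <- g + 1L
      pos <- pos + g
    }
  }
  list(match = TRUE, start = starts[1L], end = pos - 1L,
       spans = spans)
}

# Evaluate an expression under a temporary RNG seed, restoring the
# caller's RNG state afterwards (bit-exact reproducibility without side
# effects).
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

msa_group_rows <- function(msa, group) which(msa$groups == group)

#' Detect evolutionary rate shifts between two groups of an alignment
#'
#' Per column (gap-majority columns skipped): type-ii shifts are columns
#' conserved as one residue in group A and as a different residue in
#' group B (both conservations at or above the threshold, computed among
#' non-gap residues); type-i shifts are conserved in exactly one group.
#'
#' @param msa A [grouped_msa()].
#' @param groups Character vector of the two group labels (default: first
#'   two groups).
#' @param conservation_threshold Minimum within-group consensus fraction
#'   (default 0.9).
#' @param max_gap_fraction Columns with more gaps than this are skipped.
#' @return data.frame `column`, `group_a_residue`, `group_b_residue`,
#'   `conservation_a`, `conservation_b`, `type` (`"i"` or `"ii"`).
#' @export
type_ii_shifts <- function(msa, groups = NULL,
                           conservation_threshold = 0.9,
                           max_gap_fraction = 0.5) {
  stopifnot(inherits(msa, "GroupedMsa"))
  if (is.null(groups)) groups <- unique(msa$groups)[1:2]
  if (!all(groups %in% msa$groups))
    stop("group absent from alignment: ",
         paste(setdiff(groups, msa$groups), collapse = ", "))
  m <- msa_matrix(msa)
  ra <- m[msa_group_rows(msa, groups[1]), , drop = FALSE]
  rb <- m[msa_group_rows(msa, groups[2]), , drop = FALSE]
  out <- NULL
  for (j in seq_len(msa$length)) {
    col <- m[, j]
    if (mean(col == "-") > max_gap_fraction) next
    cons <- function(x) {
      x <- x[x != "-"]
      if (!length(x)) return(c(res = NA, frac = 0))
      tb <- sort(table(x), decreasing = TRUE)
      c(res = names(tb)[1], frac = as.numeric(tb[1]) / length(x))
    }
    a <- cons(ra[, j]); b <- cons(rb[, j])
    ca <- as.numeric(a["frac"]) >= conservation_threshold
    cb <- as.numeric(b["frac"]) >= conservation_threshold
    type <- if (ca && cb && !is.na(a["res"]) && !is.na(b["res"]) &&
                a["res"] != b["res"]) "ii"
    else if (xor(ca, cb)) "i"
    else next
    out <- rbind(out, data.frame(
      column = j, group_a_residue = unname(a["res"]),
      group_b_residue = unname(b["res"]),
      conservation_a = as.numeric(a["frac"]),
      conservation_b = as.numeric(b["frac"]),
      type = type, stringsAsFactors = FALSE))
  }
  if (is.null(out))
    out <- data.frame(column = integer(0), group_a_residue = character(0),
                      group_b_residue = character(0),
                      conservation_a = numeric(0),
                      conservation_b = numeric(0), type = character(0))
  out
}

# Trimmed z-standardization: mean/sd of the central (1 - 2*trim) mass,
# so a minority of signal columns does not inflate the null spread.
trimmed_z <- function(x, trim = 0.25) {
  ok <- is.finite(x)
  qs <- stats::quantile(x[ok], c(trim, 1 - trim), names = FALSE)
  core <- x[ok & x >= qs[1] & x <= qs[2]]
  mu <- mean(core)
  sdv <- stats::sd(core)
  if (!is.finite(sdv) || sdv == 0) sdv <- stats::sd(x[ok])
  if (!is.finite(sdv) || sdv == 0) sdv <- 1
  (x - mu) / sdv
}

#' Score alignment columns for group-specific residues
#'
#' Two complementary branches, both z-standardized across columns:
#'
#' * harmony branch: the generalized Jensen-Shannon divergence (base 2,
#'   pseudocount 0.5, normalized to `[0, 1]`) between the per-group
#'   residue profiles of the column. The similarity-oriented score
#'   `1 - divergence` is z-scored so that group-distinct columns are
#'   strongly negative (`z_score`); selection uses `z_score <
#'   z_score_threshold` (default -10).
#' * relief branch: seeded repeated subsampling (half the rows per
#'   group); per sequence, the nearest same-group neighbour (hit) and
#'   nearest other-group neighbour (miss) by whole-row identity update
#'   each column's weight by `mismatch(miss) - mismatch(hit)`. The mean
#'   weight is z-scored to `z_weight`; selection uses `z_weight >
#'   z_weight_threshold` (default 6).
#'
#' A column is `selected` when both thresholds are met. Columns with more
#' than `max_gap_fraction` gaps are excluded from standardization and
#' never selected.
#'
#' @param msa A [grouped_msa()] with >= 2 groups of >= 3 sequences.
#' @param n_subsamples Relief subsample count (default 100).
#' @param seed Integer seed (results are deterministic given it).
#' @param z_weight_threshold,z_score_threshold Selection thresholds.
#' @param pseudocount Dirichlet pseudocount per residue (default 0.5).
#' @param trim Trim fraction for the z standardization (default 0.25:
#'   quartile-based core, robust to a minority of signal columns).
#' @param max_gap_fraction Gap-exclusion threshold (default 0.5).
#' @return data.frame of class `SiteScoreTable`: `column`,
#'   `sh_divergence`, `z_score`, `relief_weight`, `z_weight`, `selected`.
#' @export
group_specific_sites <- function(msa, n_subsamples = 100, seed = 1,
                                 z_weight_threshold = 6,
                                 z_score_threshold = -10,
                                 pseudocount = 0.5, trim = 0.25,
                                 max_gap_fraction = 0.5) {
  stopifnot(inherits(msa, "GroupedMsa"))
  groups <- unique(msa$groups)
  if (length(groups) < 2L) stop("need at least 2 groups")
  sizes <- table(msa$groups)
  if (any(sizes < 3L))
    stop("every group needs at least 3 sequences (",
         paste(names(sizes)[sizes < 3], collapse = ","), " too small)")
  m <- msa_matrix(msa)
  n <- nrow(m); L <- ncol(m)
  gap_frac <- colMeans(m == "-")
  usable <- gap_frac <= max_gap_fraction

  # --- harmony branch: generalized JS divergence of group profiles
  k <- length(groups)
  ent <- function(p) {
    p <- p[p > 0]
    -sum(p * log2(p))
  }
  sh <- rep(NA_real_, L)
  prof_of <- function(rows, j) {
    cnt <- table(factor(m[rows, j], levels = AA_LETTERS))
    p <- as.numeric(cnt) + pseudocount
    p / sum(p)
  }
  rows_by_group <- lapply(groups, function(g) msa_group_rows(msa, g))
  for (j in which(usable)) {
    profs <- lapply(rows_by_group, prof_of, j = j)
    pbar <- Reduce(`+`, profs) / k
    jsd <- ent(pbar) - mean(vapply(profs, ent, numeric(1)))
    sh[j] <- jsd / log2(k)
  }
  z_score <- rep(NA_real_, L)
  z_score[usable] <- trimmed_z(1 - sh[usable], trim)

  # --- relief branch: seeded nearest hit/miss column weighting
  relief <- with_seed(seed, {
    dmat <- matrix(0L, n, n)
    for (a in seq_len(n - 1)) for (b in (a + 1):n) {
      dmat[a, b] <- dmat[b, a] <- sum(m[a, ] != m[b, ])
    }
    w <- rep(0, L)
    n_inst <- 0L
    for (rep_i in seq_len(n_subsamples)) {
      sub <- unlist(lapply(rows_by_group, function(rows)
        sort(sample(rows, max(2L, floor(length(rows) / 2))))))
      sub_groups <- msa$groups[sub]
      for (ii in seq_along(sub)) {
        i <- sub[ii]
        same <- sub[sub_groups == sub_groups[ii] & sub != i]
        other <- sub[sub_groups != sub_groups[ii]]
        hit <- same[which.min(dmat[i, same])]
        miss <- other[which.min(dmat[i, other])]
        w <- w + (m[i, ] != m[miss, ]) - (m[i, ] != m[hit, ])
        n_inst <- n_inst + 1L
      }
    }
    w / n_inst
  })
  z_weight <- rep(NA_real_, L)
  z_weight[usable] <- trimmed_z(relief[usable], trim)

  selected <- !is.na(z_score) & !is.na(z_weight) &
    z_weight > z_weight_threshold & z_score < z_score_threshold
  out <- data.frame(column = seq_len(L), sh_divergence = sh,
                    z_score = z_score, relief_weight = relief,
                    z_weight = z_weight, selected = selected)
  class(out) <- c("SiteScoreTable", "data.frame")
  out
}

#' Per-column consensus of one group
#'
#' @param msa A [grouped_msa()].
#' @param group Group label.
#' @return data.frame `column`, `consensus` (majority residue, `"-"` when
#'   gaps dominate), `frequency`.
#' @export
clade_consensus <- function(msa, group) {
  stopifnot(inherits(msa, "GroupedMsa"))
  rows <- msa_group_rows(msa, group)
  if (!length(rows)) stop("group not found: ", group)
  m <- msa_matrix(msa)[rows, , drop = FALSE]
  cons <- apply(m, 2, function(col) {
    tb <- sort(table(col), decreasing = TRUE)
    c(names(tb)[1], as.numeric(tb[1]) / length(col))
  })
  data.frame(column = seq_len(ncol(m)), consensus = cons[1, ],
             frequency = round(as.numeric(cons[2, ]), 4),
             stringsAsFactors = FALSE)
}
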