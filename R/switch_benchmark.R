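# The planted mutation-response benchmark: a response table with silent
# singles, partial one-helix movers, full switchers, a cooperative pair
# and a suppressor, evaluated end to end through the predictor stand-in
# and the switch classifier.

#' The benchmark mutation-response world
#'
#' Forty labelled mutants on the rocking-bundle native (an IO template,
#' t = 1): 20 conformation-silent singles (including the `YN` and `VY`
#' singles and the suppressor `sup`), 8 partial mutants that each
#' displace one static helix by 4 A, 8 full switchers (t = 0), the
#' cooperative pair `YN + VY` (silent alone, switched combined), the
#' suppressor combination `sw1 + sup` (near-native again) and two decoy
#' combinations `sw1 + d1/d2` that leave the switch intact.
#'
#' @return List: `table` (a [response_table()]), `sets` (list of label
#'   vectors: the mutants to model), `pairs` (label pairs scored for
#'   epistasis), `suppressor_candidates` (labels screened against `sw1`).
#' @export
benchmark_response_spec <- function() {
  partial_helices <- c("h3", "h4", "h5", "h8", "h9", "h10", "h11", "h4")
  singles <- list()
  for (k in 1:8)
    singles[[paste0("par", k)]] <-
      list(t = 1, helix_shift = stats::setNames(4, partial_helices[k]))
  for (k in 1:8) singles[[paste0("sw", k)]] <- list(t = 0)
  # YN, VY, sup, d1, d2 and sil1..sil15 are conformation-silent singles:
  # they are deliberately absent from the table (unlisted = native t)
  combos <- list()
  combos[[combo_key(c("YN", "VY"))]] <- list(t = 0)
  combos[[combo_key(c("sw1", "sup"))]] <- list(t = 0.95)
  combos[[combo_key(c("sw1", "d1"))]] <- list(t = 0)
  combos[[combo_key(c("sw1", "d2"))]] <- list(t = 0)
  table <- response_table(singles = singles, combos = combos, native_t = 1)
  sets <- c(
    lapply(paste0("sil", 1:15), identity),
    list("YN", "VY", "sup", "d1", "d2"),
    lapply(paste0("par", 1:8), identity),
    lapply(paste0("sw", 1:8), identity),
    list(c("YN", "VY"), c("sw1", "sup"), c("sw1", "d1"), c("sw1", "d2"))
  )
  list(table = table, sets = sets,
       pairs = list(c("YN", "VY"), c("sw1", "sup")),
       suppressor_candidates = c("sup", "d1", "d2"))
}

#' Run the switch/epistasis benchmark
#'
#' Simulates every benchmark mutant with the predictor stand-in at the
#' requested noise level, classifies each against the simulated native
#' model, and scores the planted epistasis pairs and the suppressor
#' screen. Planted truth verdicts are the classifications of the
#' noiseless (sigma = 0) world.
#'
#' @param ensemble A [generate_ensemble()] result.
#' @param sigma Coordinate noise s.d. in Angstroms (default 0.3).
#' @param seed Integer seed.
#' @param tau,switch_threshold,silent_threshold Classifier thresholds
#'   (defaults as in [classify_switch()]).
#' @return List: `verdicts` (data.frame `label`, `planted`, `observed`,
#'   `match`), `accuracy`, `epistasis` (data.frame with planted and
#'   observed classes), `suppressors` (the screen against `sw1`).
#' @export
run_switch_benchmark <- function(ensemble, sigma = 0.3, seed = 1,
                                 tau = 2.0, switch_threshold = 0.25,
                                 silent_threshold = 0.05) {
  spec <- benchmark_response_spec()
  signature <- ensemble$signature
  segments <- ensemble$segments

  call_world <- function(sig, seed_base) {
    native <- simulate_mutant_response(ensemble, "wt", spec$table,
                                       sigma = sig, seed = seed_base)
    calls <- list()
    for (k in seq_along(spec$sets)) {
      labels <- spec$sets[[k]]
      mut <- simulate_mutant_response(ensemble, labels, spec$table,
                                      sigma = sig, seed = seed_base + k)
      prof <- deviation_profile(mut, native, segments = segments)
      calls[[combo_key(labels)]] <- classify_switch(
        prof, label = combo_key(labels), tau = tau,
        switch_threshold = switch_threshold,
        silent_threshold = silent_threshold, signature = signature)
    }
    calls
  }
  truth_calls <- call_world(0, 0)
  obs_calls <- call_world(sigma, seed * 1000L)

  labels <- names(truth_calls)
  verdicts <- data.frame(
    label = labels,
    planted = vapply(truth_calls, `[[`, character(1), "verdict"),
    observed = vapply(obs_calls, `[[`, character(1), "verdict"),
    stringsAsFactors = FALSE)
  verdicts$match <- verdicts$planted == verdicts$observed

  ep_rows <- NULL
  for (pair in spec$pairs) {
    key <- combo_key(pair)
    planted <- epistasis_score(truth_calls[[pair[1]]],
                               truth_calls[[pair[2]]], truth_calls[[key]])
    observed <- epistasis_score(obs_calls[[pair[1]]],
                                obs_calls[[pair[2]]], obs_calls[[key]])
    ep_rows <- rbind(ep_rows, data.frame(
      pair = key, planted = planted$classification,
      planted_epsilon = round(planted$epsilon, 4),
      observed = observed$classification,
      observed_epsilon = round(observed$epsilon, 4),
      stringsAsFactors = FALSE))
  }

  combined <- lapply(spec$suppressor_candidates, function(cand)
    obs_calls[[combo_key(c("sw1", cand))]])
  names(combined) <- spec$suppressor_candidates
  suppressors <- suppressor_screen(obs_calls[["sw1"]], combined)

  list(verdicts = verdicts, accuracy = mean(verdicts$match),
       epistasis = ep_rows, suppressors = suppressors,
       truth_calls = truth_calls, observed_calls = obs_calls)
}
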