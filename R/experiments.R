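# The familiarization/test harness. Experiment 1 imposes presentation
# orders defined by mean successive distance (max / min / med / random);
# Experiment 2 lets the model choose its own order under one of the four
# selection policies. Both run 24 seeded networks per condition, with run r
# of every condition initialized from base_seed + r so conditions are
# compared across matched initializations.

EXP1_CONDITIONS <- c("max", "min", "med", "random")

#' Familiarize the network on one stimulus
#'
#' Repeatedly applies [train_sweep()] to the stimulus, up to `max_sweeps`
#' sweeps or until its post-update SSE falls below `threshold` (the model
#' "looks away" once the stimulus is encoded). After every sweep the full
#' training set is probed with no weight updating; the mean probe SSE per
#' sweep is the recorded looking index.
#'
#' @param state a `network_state`.
#' @param stimulus the current stimulus vector.
#' @param training_set matrix of all 8 training stimuli (probe set).
#' @param params a [network_params()].
#' @return A list with the updated `state` and `trial`, a record holding
#'   `sweeps_used`, `probe_sse` (length `sweeps_used`) and
#'   `final_stimulus_sse`.
#' @export
familiarize_on_stimulus <- function(state, stimulus, training_set,
                                    params = network_params()) {
  probe_means <- numeric(params$max_sweeps)
  s <- 0L
  repeat {
    s <- s + 1L
    up <- train_sweep(state, stimulus, params$eta)
    state <- up$state
    probe_means[s] <- mean(probe_error(state, training_set))
    if ((is.finite(params$threshold) && up$sse_after < params$threshold) ||
        s >= params$max_sweeps) break
  }
  list(state = state,
       trial = list(sweeps_used = s, probe_sse = probe_means[seq_len(s)],
                    final_stimulus_sse = up$sse_after))
}

#' Novelty-preference test phase
#'
#' Presents the three novel test stimuli (one category-central, two
#' category-peripheral) for a single forward sweep each, with no weight
#' updates, and computes the proportion of total test SSE falling on the
#' peripheral items: `mean(peripheral SSE) / (mean(peripheral SSE) +
#' central SSE)`. Values above 0.5 indicate a category centered on the
#' prototype (relatively larger error, i.e. longer looking, to the
#' peripheral items).
#'
#' @param state a trained `network_state`.
#' @param set a [stimulus_set()].
#' @return A list with `sse_central`, `sse_peripheral` (length 2) and
#'   `prop_peripheral`.
#' @export
test_phase <- function(state, set) {
  sse_central <- probe_error(state, set$central)
  sse_peripheral <- probe_error(state, set$peripherals)
  mp <- mean(sse_peripheral)
  if (mp + sse_central == 0)
    stop("all test SSEs are zero; peripheral proportion is undefined")
  list(sse_central = sse_central, sse_peripheral = sse_peripheral,
       prop_peripheral = mp / (mp + sse_central))
}

run_one <- function(label, seed, order_idx, set, params, policy = NULL) {
  training <- set$training
  seed <- as.integer(seed)
  state <- init_network(params, seed)
  n <- nrow(training)
  trials <- vector("list", n)
  if (!is.null(policy)) {
    # selection is interleaved with learning: the choice at trial t depends
    # on the weights after familiarization on trials 1..t-1
    chosen <- integer(n)
    remaining <- seq_len(n)
    current <- NULL
    for (t in seq_len(n)) {
      pick <- select_next(policy, state, training[remaining, , drop = FALSE],
                          current)
      chosen[t] <- remaining[pick]
      current <- training[chosen[t], ]
      remaining <- remaining[-pick]
      fam <- familiarize_on_stimulus(state, current, training, params)
      state <- fam$state
      trials[[t]] <- c(list(trial = t,
                            stimulus_id = rownames(training)[chosen[t]]),
                       fam$trial)
    }
  } else {
    chosen <- order_idx
    for (t in seq_len(n)) {
      stim <- training[chosen[t], ]
      fam <- familiarize_on_stimulus(state, stim, training, params)
      state <- fam$state
      trials[[t]] <- c(list(trial = t,
                            stimulus_id = rownames(training)[chosen[t]]),
                       fam$trial)
    }
  }
  tp <- test_phase(state, set)
  structure(list(label = label, seed = seed,
                 order = rownames(training)[chosen], order_idx = chosen,
                 trials = trials, sse_central = tp$sse_central,
                 sse_peripheral = tp$sse_peripheral,
                 prop_peripheral = tp$prop_peripheral),
            class = "run_result")
}

#' @export
print.run_result <- function(x, ...) {
  cat("<run_result>", x$label, "seed", x$seed, "\n")
  cat("order:", paste(x$order, collapse = " -> "), "\n")
  cat(sprintf("prop_peripheral: %.3f\n", x$prop_peripheral))
  invisible(x)
}

#' Run Experiment 1 (imposed presentation orders)
#'
#' For each distance condition, trains `n_runs` independently initialized
#' networks (run r seeded with `base_seed + r`), each on that condition's
#' r-th presentation order, then applies the novelty-preference test.
#'
#' @param set a [stimulus_set()].
#' @param conditions subset of `c("max", "min", "med", "random")`.
#' @param n_runs networks per condition (default 24).
#' @param params a [network_params()].
#' @param base_seed integer; run r of every condition uses `base_seed + r`.
#' @return A list of `run_result` objects (`length(conditions) * n_runs`).
#' @export
run_experiment1 <- function(set, conditions = EXP1_CONDITIONS, n_runs = 24L,
                            params = network_params(), base_seed = 0L) {
  conditions <- match.arg(conditions, EXP1_CONDITIONS, several.ok = TRUE)
  all_seqs <- enumerate_sequences(set$training)
  out <- list()
  for (cond in conditions) {
    orders <- build_condition_orders(all_seqs, cond, n_sets = n_runs,
                                     seed = if (cond == "random") base_seed)
    for (r in seq_len(n_runs))
      out[[length(out) + 1L]] <-
        run_one(cond, base_seed + r, orders[r, ], set, params)
  }
  out
}

#' Run Experiment 2 (curiosity-driven stimulus selection)
#'
#' For each selection policy, runs `n_runs` networks (run r seeded with
#' `base_seed + r`). Each run iterates 8 trials of: score the remaining
#' stimuli against the current weights, select the maximizer (no weight
#' update during selection), then familiarize on it; the test phase follows
#' trial 8. The chosen order is recorded per run.
#'
#' @param set a [stimulus_set()].
#' @param policies subset of
#'   `c("curiosity", "objective", "subjective", "plasticity")`.
#' @inheritParams run_experiment1
#' @return A list of `run_result` objects.
#' @export
run_experiment2 <- function(set, policies = POLICY_KINDS, n_runs = 24L,
                            params = network_params(), base_seed = 0L) {
  policies <- match.arg(policies, POLICY_KINDS, several.ok = TRUE)
  out <- list()
  for (pol in policies)
    for (r in seq_len(n_runs))
      out[[length(out) + 1L]] <-
        run_one(pol, base_seed + r, NULL, set, params, policy = pol)
  out
}

#' Tidy per-sweep results
#'
#' @param results list of `run_result` objects.
#' @return A data frame with one row per (condition/policy, seed, trial,
#'   sweep) and the mean probe SSE over the training set at that sweep.
#' @export
results_to_df <- function(results) {
  do.call(rbind, lapply(results, function(rr) {
    do.call(rbind, lapply(rr$trials, function(tr)
      data.frame(label = rr$label, seed = rr$seed, trial = tr$trial,
                 stimulus_id = tr$stimulus_id,
                 sweep = seq_len(tr$sweeps_used), probe_sse = tr$probe_sse,
                 row.names = NULL)))
  }))
}

#' Per-run summary table
#'
#' @param results list of `run_result` objects.
#' @return A data frame with one row per run: label, seed, chosen/imposed
#'   order (ids joined by `>`), test SSEs and the peripheral proportion.
#' @export
run_summary_df <- function(results) {
  do.call(rbind, lapply(results, function(rr)
    data.frame(label = rr$label, seed = rr$seed,
               order = paste(rr$order, collapse = ">"),
               sse_central = rr$sse_central,
               sse_peripheral1 = rr$sse_peripheral[1L],
               sse_peripheral2 = rr$sse_peripheral[2L],
               prop_peripheral = rr$prop_peripheral, row.names = NULL)))
}
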