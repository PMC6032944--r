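# Intrinsically motivated stimulus selection: the four policies scoring
# candidate stimuli against the current network state. Scoring is a pure
# novelty-detection step -- a forward pass with no weight update.

POLICY_KINDS <- c("curiosity", "objective", "subjective", "plasticity")

#' Curiosity score of a candidate stimulus
#'
#' The summed absolute per-unit weight-update magnitude
#' `sum_k |(i_k - o_k) o_k (1 - o_k)|`: subjective novelty gated by
#' plasticity. A curious learner picks the candidate maximizing this, i.e.
#' the stimulus affording the largest learning step. Per dimension the score
#' is at most 4/27 (attained at o = 1/3 for i = 1), so the total is below
#' 16/27.
#'
#' @param state a `network_state`.
#' @param stimulus numeric feature vector.
#' @return Non-negative scalar; the state is never modified.
#' @export
curiosity_score <- function(state, stimulus) {
  act <- forward(state, stimulus)
  sum(abs((act$input - act$output) * act$output * (1 - act$output)))
}

#' Subjective novelty score
#'
#' Summed absolute discrepancy `sum_k |i_k - o_k|` between a candidate and
#' the model's current reconstruction of it: novelty relative to learning
#' history, ignoring readiness to learn.
#'
#' @inheritParams curiosity_score
#' @return Non-negative scalar below 4 (sigmoid outputs are inside (0, 1)).
#' @export
novelty_score <- function(state, stimulus) {
  act <- forward(state, stimulus)
  sum(abs(act$input - act$output))
}

#' Plasticity score
#'
#' Summed sigmoid derivative `sum_k o_k (1 - o_k)` of the outputs evoked by
#' a candidate: how ready the model is to change, disregarding how much the
#' stimulus would actually teach it. Maximal (1.0) when every output sits
#' at 0.5.
#'
#' @inheritParams curiosity_score
#' @return Scalar in (0, 1].
#' @export
plasticity_score <- function(state, stimulus) {
  act <- forward(state, stimulus)
  sum(act$output * (1 - act$output))
}

#' Objective complexity score
#'
#' The Euclidean distance from the currently processed stimulus to a
#' candidate: novelty objectively present in the environment, independent of
#' the learner's state.
#'
#' @param current the stimulus currently being processed (errors if `NULL`;
#'   the experiment runner draws the first stimulus at random instead).
#' @param candidate a candidate feature vector.
#' @return Non-negative scalar distance.
#' @export
objective_complexity_score <- function(current, candidate) {
  if (is.null(current))
    stop("objective complexity is undefined without a current stimulus")
  euclidean_distance(current, candidate)
}

#' Select the next stimulus under a policy
#'
#' Picks, without replacement, the remaining stimulus with the maximal score
#' under the given policy. The three state-dependent policies (curiosity,
#' subjective novelty, plasticity) score against the current weights from
#' trial 1 onward; objective complexity has no anchor on trial 1 and draws
#' uniformly at random, thereafter maximizing distance from the current
#' stimulus. Exact score ties are broken uniformly at random. Selection
#' never updates weights.
#'
#' @param policy one of `"curiosity"`, `"objective"`, `"subjective"`,
#'   `"plasticity"`.
#' @param state a `network_state`.
#' @param remaining numeric matrix of candidate stimuli (rows), with
#'   rownames as ids.
#' @param current the currently processed stimulus vector, or `NULL` on
#'   trial 1.
#' @return The row index (into `remaining`) of the selected stimulus, with
#'   the score vector in attribute `scores` (`NA` for the random first
#'   objective pick).
#' @export
select_next <- function(policy, state, remaining, current = NULL) {
  policy <- match.arg(policy, POLICY_KINDS)
  remaining <- if (is.matrix(remaining)) remaining else
    matrix(remaining, nrow = 1L)
  if (nrow(remaining) == 0L) stop("no remaining stimuli to select from")
  if (policy == "objective" && is.null(current)) {
    pick <- sample.int(nrow(remaining), 1L)
    return(structure(pick, scores = rep(NA_real_, nrow(remaining))))
  }
  scores <- apply(remaining, 1L, function(s) switch(policy,
    curiosity = curiosity_score(state, s),
    subjective = novelty_score(state, s),
    plasticity = plasticity_score(state, s),
    objective = objective_complexity_score(current, s)))
  best <- which(scores == max(scores))
  pick <- if (length(best) == 1L) best else
    best[sample.int(length(best), 1L)]
  structure(pick, scores = as.numeric(scores))
}
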