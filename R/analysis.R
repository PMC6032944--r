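# Statistics and sequence-complexity characterization: tests of the
# peripheral-SSE categorization index against chance and between
# conditions, habituation block contrasts, and ranking of chosen
# presentation sequences within the full permutation space.

#' One-sample Wilcoxon signed-rank test against chance
#'
#' Tests whether peripheral-SSE proportions exceed chance (`mu`, default
#' 0.5). The statistic V is the sum of the ranks of the positive
#' differences (zero differences dropped, tied absolute differences given
#' average ranks); with all 24 proportions above chance V attains its
#' maximum n(n+1)/2 = 300.
#'
#' @param values numeric vector of proportions in [0, 1].
#' @param mu chance level (default 0.5).
#' @return A list with `V`, two-sided `p` and `n` (non-zero differences).
#' @export
wilcoxon_signed_rank_vs_chance <- function(values, mu = 0.5) {
  d <- values - mu
  d <- d[d != 0]
  if (length(d) == 0L)
    stop("all differences from chance are zero; the test is undefined")
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  p <- suppressWarnings(stats::wilcox.test(values[values != mu],
                                           mu = mu)$p.value)
  list(V = V, p = p, n = length(d))
}

#' Kruskal-Wallis rank test across conditions
#'
#' @param groups named list of numeric vectors, one per condition.
#' @return A list with `H`, `df` and `p`.
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2L) stop("need at least 2 groups")
  if (any(lengths(groups) == 0L)) stop("groups must be non-empty")
  if (length(unique(unlist(groups))) == 1L)
    return(list(H = 0, df = length(groups) - 1L, p = 1))
  kt <- stats::kruskal.test(groups)
  list(H = unname(kt$statistic), df = unname(kt$parameter), p = kt$p.value)
}

trial_looking <- function(rr) {
  vapply(rr$trials, function(tr) mean(tr$probe_sse), numeric(1L))
}

#' First- versus final-block habituation contrast
#'
#' Per run, the mean of per-trial looking (mean probe SSE over the training
#' set) across the first `block` trials and the final `block` trials.
#' Habituation predicts first > last.
#'
#' @param results list of `run_result` objects with 8 trials each.
#' @param block trials per block (default 3).
#' @return Data frame with one row per run: label, seed, `first_block_mean`,
#'   `last_block_mean`.
#' @export
block_contrast <- function(results, block = 3L) {
  do.call(rbind, lapply(results, function(rr) {
    look <- trial_looking(rr)
    n <- length(look)
    if (n != 8L) stop("expected 8 trials per run, got ", n)
    data.frame(label = rr$label, seed = rr$seed,
               first_block_mean = mean(look[seq_len(block)]),
               last_block_mean = mean(look[seq.int(n - block + 1L, n)]),
               row.names = NULL)
  }))
}

ROUND_ED <- 9L  # distances summed in different orders agree to ~1e-12

#' Characterize a presentation sequence within the permutation space
#'
#' Ranks a sequence's mean successive distance among the unique mean-ED
#' values of all enumerated permutations (rank 1 = largest, i.e. most
#' objectively complex), and computes per-step distance ranks: at each
#' trial t >= 2, the chosen step's Euclidean distance is ranked against the
#' distances from the previous stimulus to every then-remaining candidate
#' (1 = maximal; ties share the better rank).
#'
#' @param order_idx integer permutation of training-stimulus indices.
#' @param all_seqs result of [enumerate_sequences()] for the same training
#'   set.
#' @param training the training-stimulus matrix.
#' @return A list with `order_idx`, `mean_ed`, `mean_ed_rank` (from the
#'   top), `n_unique`, `step_eds`, `step_ranks` and `step_totals`
#'   (candidates available at each step).
#' @export
characterize_sequence <- function(order_idx, all_seqs, training) {
  n <- nrow(training)
  if (!identical(sort(as.integer(order_idx)), seq_len(n)))
    stop("order is not a permutation of the training stimuli")
  D <- as.matrix(stats::dist(training))
  eds <- D[cbind(order_idx[-n], order_idx[-1L])]
  med <- round(mean(eds), ROUND_ED)
  uniq <- sort(unique(round(all_seqs$mean_ed, ROUND_ED)), decreasing = TRUE)
  rank_top <- match(med, uniq)
  if (is.na(rank_top)) stop("sequence mean ED not found in enumeration")
  step_ranks <- integer(n - 1L)
  step_totals <- integer(n - 1L)
  for (t in 2:n) {
    cand <- order_idx[t:n]
    cand_eds <- round(D[order_idx[t - 1L], cand], ROUND_ED)
    step_totals[t - 1L] <- length(cand)
    step_ranks[t - 1L] <- rank(-cand_eds, ties.method = "min")[1L]
  }
  list(order_idx = as.integer(order_idx), mean_ed = mean(eds),
       mean_ed_rank = rank_top, n_unique = length(uniq),
       step_eds = unname(eds), step_ranks = step_ranks,
       step_totals = step_totals)
}

#' Format an ED rank as "rank/total"
#'
#' @param rank,total integers.
#' @return Character like `"1/7"`.
#' @export
format_ed_rank <- function(rank, total) paste0(rank, "/", total)

#' Summarize an experiment's run results
#'
#' Per condition/policy: the median peripheral proportion with the
#' signed-rank test against chance; pairwise two-sample Wilcoxon (Mann-
#' Whitney) tests between conditions, Bonferroni-corrected; and the tally
#' of distinct presentation sequences (of interest when the model chose
#' its own orders).
#'
#' @param results list of `run_result` objects, or an already-tidied
#'   [run_summary_df()] data frame.
#' @return A list with data frames `medians`, `pairwise` and
#'   `sequence_tally`.
#' @export
summarize_experiment <- function(results) {
  if (length(results) == 0L) stop("no results to summarize")
  summ <- if (is.data.frame(results)) results else run_summary_df(results)
  labs <- unique(summ$label)
  props <- split(summ$prop_peripheral, factor(summ$label, levels = labs))
  medians <- do.call(rbind, lapply(labs, function(l) {
    wt <- wilcoxon_signed_rank_vs_chance(props[[l]])
    data.frame(label = l, n = length(props[[l]]),
               median_prop_peripheral = stats::median(props[[l]]),
               V = wt$V, p_vs_chance = wt$p, row.names = NULL)
  }))
  pairwise <- NULL
  if (length(labs) > 1L) {
    pairs <- utils::combn(labs, 2L)
    pairwise <- do.call(rbind, apply(pairs, 2L, function(pr) {
      wt <- suppressWarnings(stats::wilcox.test(props[[pr[1L]]],
                                                props[[pr[2L]]]))
      data.frame(a = pr[1L], b = pr[2L], W = unname(wt$statistic),
                 p = wt$p.value, row.names = NULL)
    }))
    pairwise$p_bonferroni <- stats::p.adjust(pairwise$p, "bonferroni")
  }
  tally <- do.call(rbind, lapply(labs, function(l) {
    orders <- summ$order[summ$label == l]
    counts <- sort(table(orders), decreasing = TRUE)
    data.frame(label = l, n_distinct_orders = length(counts),
               modal_order = names(counts)[1L],
               modal_count = as.integer(counts[1L]), row.names = NULL)
  }))
  list(medians = medians, pairwise = pairwise, sequence_tally = tally)
}

#' Optimum of the curiosity function
#'
#' For a maximally novel input feature (i = 1), numerically maximizes the
#' per-unit curiosity function (i - o) o (1 - o) over the output activation
#' o in [0, 1]. The maximizer is o = 1/3 (analytically, the root of
#' (1 - o)(1 - 3o)), so the subjective novelty i - o at the optimum is
#' 2/3 -- about 0.7: learning is greatest when novelty and plasticity are
#' both intermediate but shifted toward the high-novelty end.
#'
#' @param i input value (default 1).
#' @return A list with `o_star`, `novelty_at_max` (= i - o_star) and
#'   `value` (the function maximum).
#' @export
curiosity_optimum <- function(i = 1) {
  f <- function(o) (i - o) * o * (1 - o)
  opt <- stats::optimize(f, c(0, 1), maximum = TRUE, tol = 1e-10)
  list(o_star = opt$maximum, novelty_at_max = i - opt$maximum,
       value = opt$objective)
}
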