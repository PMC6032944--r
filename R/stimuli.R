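# Stimulus construction, normalization, sequence enumeration and the
# distance-defined presentation-order conditions.

FEATURE_NAMES <- c("ear_separation", "neck_length", "leg_length", "tail_width")

#' Construct a stimulus set
#'
#' A stimulus set holds the 11 items of a Younger-style familiarization /
#' novelty-preference design: 8 training exemplars, 1 category-central test
#' item (every feature at the normalized midpoint 0.5) and 2 category-
#' peripheral test items (every feature at a normalized extreme, 0 or 1).
#' Feature values must already be normalized to [0, 1]; use
#' [normalize_features()] to build a set from raw feature values.
#'
#' @param training numeric matrix, 8 rows x 4 features in [0, 1], rownames are
#'   stimulus ids.
#' @param central numeric vector of 4 features, all equal to 0.5.
#' @param peripherals numeric matrix, 2 rows x 4 features, each entry 0 or 1.
#' @return An object of class `stimulus_set` with elements `training`,
#'   `central` and `peripherals`.
#' @export
stimulus_set <- function(training, central, peripherals) {
  training <- as.matrix(training)
  peripherals <- as.matrix(peripherals)
  central <- as.numeric(central)
  if (nrow(training) != 8L || ncol(training) != 4L)
    stop("training must be an 8 x 4 matrix")
  if (length(central) != 4L)
    stop("central must have 4 features")
  if (nrow(peripherals) != 2L || ncol(peripherals) != 4L)
    stop("peripherals must be a 2 x 4 matrix")
  if (is.null(rownames(training)))
    rownames(training) <- paste0("train", seq_len(8))
  if (is.null(rownames(peripherals)))
    rownames(peripherals) <- c("peripheral1", "peripheral2")
  colnames(training) <- colnames(peripherals) <- FEATURE_NAMES
  all_vals <- rbind(training, central, peripherals)
  if (any(!is.finite(all_vals)) || any(all_vals < 0) || any(all_vals > 1))
    stop("all features must be finite and in [0, 1]")
  if (anyDuplicated(training))
    stop("training stimuli must be unique")
  if (!all(abs(central - 0.5) < 1e-9))
    stop("central test stimulus must sit at the per-feature midpoint (0.5)")
  if (!all(peripherals %in% c(0, 1)))
    stop("peripheral test features must be at the extremes (0 or 1)")
  test_rows <- rbind(central, peripherals)
  for (r in seq_len(nrow(test_rows)))
    if (any(apply(training, 1L, function(tr) all(tr == test_rows[r, ]))))
      stop("test stimuli must not be members of the training set")
  structure(list(training = training, central = central,
                 peripherals = peripherals),
            class = "stimulus_set")
}

#' @export
print.stimulus_set <- function(x, ...) {
  cat("<stimulus_set> 8 training + 1 central + 2 peripheral items,",
      "4 features each\n")
  cat("training ids:", paste(rownames(x$training), collapse = ", "), "\n")
  invisible(x)
}

#' Min-max normalize raw feature values into a stimulus set
#'
#' Each feature column is linearly rescaled over all 11 stimuli so its
#' smallest raw value maps to 0 and its largest to 1. With raw dimensions on
#' a symmetric scale this places the category-central test item at 0.5 on
#' every feature and the peripheral items at the extremes.
#'
#' @param raw_table data frame with columns `id`, `role` (one of `train`,
#'   `test_central`, `test_peripheral`) and `f1`..`f4` (raw feature values).
#' @return A [stimulus_set()].
#' @export
normalize_features <- function(raw_table) {
  validate_stimulus_table(raw_table)
  feats <- as.matrix(raw_table[, c("f1", "f2", "f3", "f4")])
  mode(feats) <- "numeric"
  rng <- apply(feats, 2L, range)
  span <- rng[2L, ] - rng[1L, ]
  if (any(span == 0))
    stop("feature '", FEATURE_NAMES[which(span == 0)[1L]],
         "' is constant across stimuli; cannot normalize a zero range")
  norm <- sweep(sweep(feats, 2L, rng[1L, ], "-"), 2L, span, "/")
  rownames(norm) <- raw_table$id
  stimulus_set(
    training = norm[raw_table$role == "train", , drop = FALSE],
    central = norm[raw_table$role == "test_central", ],
    peripherals = norm[raw_table$role == "test_peripheral", , drop = FALSE]
  )
}

validate_stimulus_table <- function(tab) {
  need <- c("id", "role", "f1", "f2", "f3", "f4")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols))
    stop("stimulus table is missing columns: ",
         paste(missing_cols, collapse = ", "))
  feats <- suppressWarnings(
    vapply(tab[, c("f1", "f2", "f3", "f4")],
           function(col) as.numeric(as.character(col)), numeric(nrow(tab))))
  bad <- which(apply(matrix(feats, nrow = nrow(tab)), 1L,
                     function(r) any(!is.finite(r))))
  if (length(bad))
    stop("non-numeric or missing feature values in row(s): ",
         paste(tab$id[bad], collapse = ", "))
  counts <- table(factor(tab$role,
                         levels = c("train", "test_central", "test_peripheral")))
  if (counts[["train"]] != 8L)
    stop("expected 8 'train' rows, found ", counts[["train"]])
  if (counts[["test_central"]] != 1L)
    stop("expected 1 'test_central' row, found ", counts[["test_central"]])
  if (counts[["test_peripheral"]] != 2L)
    stop("expected 2 'test_peripheral' rows, found ",
         counts[["test_peripheral"]])
  invisible(tab)
}

#' Built-in fixture stimulus set
#'
#' A structure-faithful synthetic stand-in for the Younger-style animal
#' stimuli: 8 training exemplars on a discrete 1-5 raw scale spanning each of
#' the 4 features, a central test item at every feature's midpoint (raw 3)
#' and two peripheral test items at the feature extremes (all-1 and all-5).
#' The exact original dimension values are not reproduced; this fixture only
#' emulates their structure and is replaceable via [read_stimulus_csv()].
#'
#' @return A normalized [stimulus_set()].
#' @export
fixture_stimuli <- function() {
  normalize_features(fixture_raw_table())
}

fixture_raw_table <- function() {
  data.frame(
    id = c(paste0("train", 1:8), "central", "peripheral1", "peripheral2"),
    role = c(rep("train", 8), "test_central", rep("test_peripheral", 2)),
    rbind(
      c(1, 1, 5, 5), c(5, 5, 1, 1), c(1, 5, 1, 5), c(5, 1, 5, 1),
      c(2, 2, 4, 4), c(4, 4, 2, 2), c(2, 4, 2, 4), c(4, 2, 4, 2),
      c(3, 3, 3, 3), c(1, 1, 1, 1), c(5, 5, 5, 5)
    ) |> `colnames<-`(c("f1", "f2", "f3", "f4")),
    stringsAsFactors = FALSE
  )
}

#' Read / write a stimulus set as CSV
#'
#' The CSV schema has columns `id,role,f1,f2,f3,f4` with `role` in
#' `train` / `test_central` / `test_peripheral`; values may be raw (they are
#' min-max normalized on read) or already normalized (normalization is
#' idempotent on [0, 1]-spanning columns).
#'
#' @param path file path.
#' @return `read_stimulus_csv` returns a [stimulus_set()];
#'   `write_stimulus_csv` invisibly returns `path`.
#' @export
read_stimulus_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  normalize_features(tab)
}

#' @param set a [stimulus_set()].
#' @rdname read_stimulus_csv
#' @export
write_stimulus_csv <- function(set, path) {
  stopifnot(inherits(set, "stimulus_set"))
  feats <- rbind(set$training, central = set$central, set$peripherals)
  tab <- data.frame(
    id = rownames(feats),
    role = c(rep("train", 8), "test_central", rep("test_peripheral", 2)),
    feats, row.names = NULL
  )
  names(tab)[3:6] <- c("f1", "f2", "f3", "f4")
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Euclidean distance between two stimuli
#'
#' @param a,b numeric feature vectors of equal length (4 in the shipped
#'   experiments).
#' @return Non-negative scalar distance.
#' @export
euclidean_distance <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b))
    stop("stimuli must have the same number of features")
  sqrt(sum((a - b)^2))
}

#' Mean successive Euclidean distance of a presentation sequence
#'
#' The single overall perceptual-distance value of a sequence: the arithmetic
#' mean of the Euclidean distances between each consecutive pair.
#'
#' @param seq_mat numeric matrix, one stimulus per row, presentation order.
#' @return Scalar mean of the `nrow - 1` successive distances.
#' @export
mean_successive_distance <- function(seq_mat) {
  seq_mat <- as.matrix(seq_mat)
  n <- nrow(seq_mat)
  if (n < 2L) stop("a sequence needs at least 2 stimuli")
  d <- sqrt(rowSums((seq_mat[-1L, , drop = FALSE] -
                       seq_mat[-n, , drop = FALSE])^2))
  mean(d)
}

# Lexicographic enumeration of all permutations of 1..n. The enumeration
# order is part of the contract: the medium-distance condition is defined by
# positions in a stable sort that falls back on this order.
permutations_lex <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  rec <- function(v) {
    if (length(v) == 1L) return(matrix(v, 1L, 1L))
    do.call(rbind, lapply(seq_along(v), function(i)
      cbind(v[i], rec(v[-i]), deparse.level = 0)))
  }
  rec(seq_len(n))
}

#' Enumerate all presentation sequences of the training stimuli
#'
#' Generates every permutation of the training items (8! = 40,320 for the
#' shipped 8-item task) in lexicographic order of stimulus indices, with each
#' sequence's mean successive Euclidean distance.
#'
#' @param training numeric matrix of training stimuli (rows) x features.
#' @param n_expected required number of training stimuli (default 8; tests
#'   may pass smaller toy sets).
#' @return A list with `orders` (integer matrix, one permutation per row) and
#'   `mean_ed` (numeric vector of mean successive distances).
#' @export
enumerate_sequences <- function(training, n_expected = 8L) {
  training <- as.matrix(training)
  n <- nrow(training)
  if (n != n_expected)
    stop("expected ", n_expected, " training stimuli, got ", n)
  if (anyDuplicated(training)) stop("training stimuli must be unique")
  D <- as.matrix(stats::dist(training))
  P <- permutations_lex(n)
  ed_sum <- numeric(nrow(P))
  for (j in seq_len(n - 1L))
    ed_sum <- ed_sum + D[cbind(P[, j], P[, j + 1L])]
  list(orders = P, mean_ed = ed_sum / (n - 1L))
}

#' Select presentation orders for a distance-defined condition
#'
#' Implements the four order conditions: `max` takes the `n_sets` sequences
#' with the largest mean successive distance, `min` the smallest, `med` the
#' `n_sets` consecutive sequences centered on the median position of the
#' ascending stable sort (positions 20,149-20,172 of 40,320 for the 8-item
#' task, set 20,160 being the median), and `random` draws permutations
#' uniformly. Ties in mean distance are broken by enumeration order.
#'
#' @param all_seqs result of [enumerate_sequences()].
#' @param condition one of `"max"`, `"min"`, `"med"`, `"random"`.
#' @param n_sets number of orders to return (default 24).
#' @param seed optional integer seed for the `random` condition.
#' @return Integer matrix with `n_sets` rows, one presentation order per row,
#'   with the selected sequences' mean distances in attribute `mean_ed`.
#' @export
build_condition_orders <- function(all_seqs, condition = c("max", "min", "med",
                                                           "random"),
                                   n_sets = 24L, seed = NULL) {
  condition <- match.arg(condition)
  N <- nrow(all_seqs$orders)
  if (n_sets < 1L) stop("n_sets must be >= 1")
  if (n_sets > N) stop("n_sets exceeds the number of sequences (", N, ")")
  idx <- switch(condition,
    max = order(-all_seqs$mean_ed)[seq_len(n_sets)],
    min = order(all_seqs$mean_ed)[seq_len(n_sets)],
    med = {
      asc <- order(all_seqs$mean_ed)
      m <- ceiling(N / 2)
      from <- m - ceiling(n_sets / 2) + 1L
      if (from < 1L || from + n_sets - 1L > N)
        stop("n_sets too large for a centered medium-distance block")
      asc[seq.int(from, length.out = n_sets)]
    },
    random = {
      if (!is.null(seed)) set.seed(seed)
      sample.int(N, n_sets, replace = FALSE)
    })
  out <- all_seqs$orders[idx, , drop = FALSE]
  attr(out, "mean_ed") <- all_seqs$mean_ed[idx]
  out
}
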