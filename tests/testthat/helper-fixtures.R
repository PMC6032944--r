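# Shared fixtures and independent oracles.

# Collinear 3-stimulus toy set: pairwise distances are 1 (a-b), 1 (b-c),
# 2 (a-c), so order properties can be brute-forced by hand.
toy3 <- function() {
  m <- rbind(a = c(0, 0, 0, 0), b = c(0.5, 0.5, 0.5, 0.5), c = c(1, 1, 1, 1))
  m
}

# Brute-force mean successive distance over all permutations of a small set,
# independent of enumerate_sequences (direct recursion over orderings).
brute_perm_eds <- function(m) {
  n <- nrow(m)
  perms <- function(v) {
    if (length(v) == 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  ps <- perms(seq_len(n))
  eds <- vapply(ps, function(p) {
    d <- 0
    for (j in seq_len(n - 1L))
      d <- d + sqrt(sum((m[p[j], ] - m[p[j + 1L], ])^2))
    d / (n - 1L)
  }, numeric(1L))
  list(perms = ps, mean_ed = eds)
}

# Central-difference gradient of 0.5 * SSE(stimulus) with respect to every
# weight and bias; the oracle against which train_sweep updates are checked.
numeric_gradient <- function(state, stimulus, h = 1e-6) {
  half_sse <- function(st) 0.5 * sse(stimulus, forward(st, stimulus)$output)
  grad <- list()
  for (nm in c("W_ih", "b_h", "W_ho", "b_o")) {
    g <- state[[nm]]
    for (k in seq_along(g)) {
      up <- state; up[[nm]][k] <- up[[nm]][k] + h
      dn <- state; dn[[nm]][k] <- dn[[nm]][k] - h
      g[k] <- (half_sse(up) - half_sse(dn)) / (2 * h)
    }
    grad[[nm]] <- g
  }
  grad
}

# Flatten a state's parameters for whole-network comparisons.
flatten_state <- function(state)
  c(as.numeric(state$W_ih), state$b_h, as.numeric(state$W_ho), state$b_o)

random_stimulus <- function() stats::runif(4)
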