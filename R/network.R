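# The 4-3-4 sigmoid autoencoder and its generalized-delta-rule training.
#
# The model reproduces its 4-feature input on 4 output units through a
# 3-unit sigmoid bottleneck; reconstruction error (SSE) is the looking-time
# proxy. The weight update follows the generalized delta rule with the input
# as target: the output-unit error term is (i - o) * o * (1 - o) -- the
# novelty term (i - o) gated by the plasticity term o(1 - o) -- multiplied
# by the presynaptic activation and the learning rate.

#' Network hyperparameters
#'
#' @param eta learning rate (> 0, default 0.1).
#' @param init_range half-width of the uniform weight initialization
#'   interval, weights drawn on `[-init_range, init_range]` (default 0.5).
#' @param use_bias include hidden and output bias weights (default TRUE).
#' @param max_sweeps maximum weight-update sweeps per familiarization trial
#'   (default 20).
#' @param threshold stop a trial once the sum squared error on the current
#'   stimulus falls below this value (default 0.01), simulating the infant
#'   looking away after fully encoding the stimulus; `Inf` disables early
#'   stopping so every trial runs the full `max_sweeps`.
#' @return A list of class `network_params`.
#' @export
network_params <- function(eta = 0.1, init_range = 0.5, use_bias = TRUE,
                           max_sweeps = 20L, threshold = 0.01) {
  stopifnot(eta > 0, init_range > 0, max_sweeps >= 1L, threshold > 0)
  structure(list(n_input = 4L, n_hidden = 3L, n_output = 4L,
                 eta = eta, init_range = init_range, use_bias = use_bias,
                 max_sweeps = as.integer(max_sweeps), threshold = threshold),
            class = "network_params")
}

#' Initialize a network
#'
#' All weights (and biases when enabled) are drawn i.i.d. uniform on
#' `[-init_range, init_range]` from the seeded generator, so the same seed
#' reproduces the same network.
#'
#' @param params a [network_params()].
#' @param seed integer seed.
#' @return A list of class `network_state` with input-to-hidden weights
#'   `W_ih` (hidden x input), hidden biases `b_h`, hidden-to-output weights
#'   `W_ho` (output x hidden), output biases `b_o`, and the seed.
#' @export
init_network <- function(params = network_params(), seed = 1L) {
  set.seed(seed)
  r <- params$init_range
  u <- function(n) stats::runif(n, -r, r)
  state <- list(
    W_ih = matrix(u(params$n_hidden * params$n_input),
                  params$n_hidden, params$n_input),
    b_h = if (params$use_bias) u(params$n_hidden) else numeric(params$n_hidden),
    W_ho = matrix(u(params$n_output * params$n_hidden),
                  params$n_output, params$n_hidden),
    b_o = if (params$use_bias) u(params$n_output) else numeric(params$n_output),
    seed = as.integer(seed)
  )
  structure(state, class = "network_state")
}

#' @export
print.network_state <- function(x, ...) {
  cat("<network_state> 4-3-4 sigmoid autoencoder, seed", x$seed, "\n")
  invisible(x)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Forward pass
#'
#' Propagates a stimulus through the network: hidden and output activations
#' are the logistic sigmoid of the summed weighted inputs. Pure; the state
#' is never modified.
#'
#' @param state a `network_state`.
#' @param stimulus numeric feature vector (length 4).
#' @return A list with `input`, `hidden` (length 3) and `output` (length 4),
#'   activations strictly inside (0, 1).
#' @export
forward <- function(state, stimulus) {
  i <- as.numeric(stimulus)
  h <- sigmoid(drop(state$W_ih %*% i) + state$b_h)
  o <- sigmoid(drop(state$W_ho %*% h) + state$b_o)
  list(input = i, hidden = h, output = o)
}

#' Sum squared error between input and output
#'
#' The model's looking-time proxy: the summed squared discrepancy between a
#' stimulus and its reconstruction.
#'
#' @param input,output numeric vectors of equal length.
#' @return Non-negative scalar, zero iff the vectors are equal.
#' @export
sse <- function(input, output) {
  input <- as.numeric(input); output <- as.numeric(output)
  if (length(input) != length(output)) stop("length mismatch")
  sum((input - output)^2)
}

#' One training sweep (forward pass plus weight update)
#'
#' Applies the generalized delta rule with the input as its own target.
#' Output-unit error terms are `delta_k = (i_k - o_k) * o_k * (1 - o_k)`;
#' hidden-to-output weights change by `eta * delta_k * h_j` (biases by
#' `eta * delta_k`), and the hidden-layer error is backpropagated through
#' the pre-update weights as `h_j (1 - h_j) * sum_k delta_k w_jk`. The
#' update equals one gradient-descent step on half the SSE.
#'
#' @param state a `network_state`.
#' @param stimulus numeric feature vector.
#' @param eta learning rate.
#' @return A list with the updated `state` and `sse_after`, the SSE on this
#'   stimulus after the update.
#' @export
train_sweep <- function(state, stimulus, eta = 0.1) {
  act <- forward(state, stimulus)
  i <- act$input; h <- act$hidden; o <- act$output
  delta_o <- (i - o) * o * (1 - o)
  delta_h <- h * (1 - h) * drop(crossprod(state$W_ho, delta_o))
  state$W_ho <- state$W_ho + eta * tcrossprod(delta_o, h)
  state$b_o <- state$b_o + eta * delta_o
  state$W_ih <- state$W_ih + eta * tcrossprod(delta_h, i)
  state$b_h <- state$b_h + eta * delta_h
  list(state = state, sse_after = sse(i, forward(state, stimulus)$output))
}

#' Probe reconstruction error without learning
#'
#' Forward-only SSE for each probe stimulus; the weights are untouched, as
#' in the familiarization index recorded after every sweep.
#'
#' @param state a `network_state`.
#' @param stimuli numeric matrix, one stimulus per row.
#' @return Numeric vector of SSE values, one per row.
#' @export
probe_error <- function(state, stimuli) {
  stimuli <- if (is.matrix(stimuli)) stimuli else matrix(stimuli, nrow = 1L)
  apply(stimuli, 1L, function(s) sse(s, forward(state, s)$output))
}

#' Serialize / restore a network state as JSON
#'
#' Flat JSON snapshot (shapes, weights, biases, seed) for reproducibility.
#'
#' @param state a `network_state`.
#' @param path file path.
#' @return `write_network_json` invisibly returns `path`;
#'   `read_network_json` returns the restored `network_state`.
#' @export
write_network_json <- function(state, path) {
  doc <- list(n_hidden = nrow(state$W_ih), n_input = ncol(state$W_ih),
              n_output = nrow(state$W_ho), W_ih = as.numeric(state$W_ih),
              b_h = state$b_h, W_ho = as.numeric(state$W_ho), b_o = state$b_o,
              seed = state$seed)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_network_json
#' @export
read_network_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(
    W_ih = matrix(doc$W_ih, doc$n_hidden, doc$n_input),
    b_h = doc$b_h,
    W_ho = matrix(doc$W_ho, doc$n_output, doc$n_hidden),
    b_o = doc$b_o,
    seed = as.integer(doc$seed)
  ), class = "network_state")
}
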