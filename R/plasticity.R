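#' Dopamine-gated Hebbian/anti-Hebbian weight update with momentum
#'
#' The plastic weight change is a first-order-momentum Hebbian rule whose
#' sign is set by the dopamine gating window:
#' `dW = mu * dW_prev + s * nu * outer(post, pre)` with `s = +1` during a
#' Hebbian window (LTP), `-1` during an anti-Hebbian window (LTD) and `0`
#' when the gate is closed (momentum still decays). Weights are clipped to
#' the bounds after the update.
#'
#' @param W weight matrix (`length(post)` x `length(pre)`).
#' @param dW_prev previous weight change (same shape; the momentum buffer).
#' @param pre presynaptic activity vector.
#' @param post postsynaptic activity vector.
#' @param mode gating mode: `"hebb"`, `"antihebb"` or `"off"`.
#' @param mu momentum constant in \[0, 1).
#' @param nu learning rate (> 0).
#' @param w_min,w_max weight bounds.
#' @return `list(W = clipped updated matrix, dW = the raw weight change)`.
#' @examples
#' hebbian_update(matrix(0, 1, 1), matrix(0, 1, 1), pre = 1, post = 1,
#'                mode = "hebb", mu = 0, nu = 0.05)
#' @export
hebbian_update <- function(W, dW_prev, pre, post, mode = "off",
                           mu = 0.5, nu = 0.01, w_min = -1, w_max = 1) {
  s <- switch(mode, hebb = 1, antihebb = -1, off = 0,
              stop("unknown gate mode: ", mode, call. = FALSE))
  dW <- mu * dW_prev
  if (s != 0) dW <- dW + (s * nu) * outer(post, pre)
  W2 <- W + dW
  W2[W2 > w_max] <- w_max
  W2[W2 < w_min] <- w_min
  list(W = W2, dW = dW)
}

#' Per-trial plasticity read-out
#'
#' The model's plasticity measure is the sum of the absolute value of all
#' potentiation (LTP) and depression (LTD) over a trial: absolute weight
#' changes accumulate — LTP and LTD do not cancel.
#'
#' @param dW_records a list of weight-change matrices (one per gated step),
#'   or a single matrix.
#' @return nonnegative scalar `sum(|dW|)` over all records.
#' @examples
#' trial_plasticity(list(matrix(0.05, 1, 1), matrix(-0.05, 1, 1)))  # 0.10
#' @export
trial_plasticity <- function(dW_records) {
  if (is.matrix(dW_records) || is.numeric(dW_records)) {
    dW_records <- list(dW_records)
  }
  sum(vapply(dW_records, function(m) sum(abs(m)), numeric(1)))
}
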