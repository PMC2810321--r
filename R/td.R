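#' Serial-compound (tapped delay line) stimulus features
#'
#' The TD dopamine block represents a conditioned stimulus as a complete
#' serial compound: feature k is active iff the most recent CS onset
#' occurred k steps ago and the stimulus is still inside its trial window.
#' At most one feature is active at a time for a single CS channel.
#'
#' @param cs_history integer/logical vector of the CS channel's presence at
#'   steps `1..now` (the last element is the current step).
#' @param n_features length of the delay line.
#' @param in_window logical; whether the trial's reward-expectation window
#'   is still open (features are forced to zero once it closes, e.g. after
#'   reward delivery or trial termination).
#' @return a numeric 0/1 vector of length `n_features`.
#' @examples
#' serial_compound(c(0, 0, 1), n_features = 5)        # onset now -> k = 0
#' serial_compound(c(0, 1, 1, 1), n_features = 5)     # onset 2 steps ago
#' @export
serial_compound <- function(cs_history, n_features, in_window = TRUE) {
  if (length(cs_history) < 1L) stop("cs_history must be nonempty", call. = FALSE)
  x <- numeric(n_features)
  if (!in_window) return(x)
  cs <- as.integer(cs_history != 0)
  onsets <- which(diff(c(0L, cs)) == 1L)
  if (!length(onsets)) return(x)
  k <- length(cs) - onsets[length(onsets)]  # steps since most recent onset
  if (k < n_features) x[k + 1L] <- 1
  x
}

#' Temporal-difference prediction error
#'
#' The dopamine signal: `delta = r(t+1) + gamma * V(t+1) - V(t)` with
#' `V = w . x`. Positive at unpredicted rewards, negative when a predicted
#' reward is omitted, near zero once predictions are accurate.
#'
#' @param w TD weight vector.
#' @param x_t feature vector at the earlier step.
#' @param x_t1 feature vector at the later step.
#' @param r_t1 reward received at the later step.
#' @param gamma discount factor in (0, 1].
#' @return scalar prediction error.
#' @export
td_error <- function(w, x_t, x_t1, r_t1 = 0, gamma = 0.98) {
  if (length(x_t) != length(w) || length(x_t1) != length(w)) {
    stop("feature vectors must have the same length as w", call. = FALSE)
  }
  r_t1 + gamma * sum(w * x_t1) - sum(w * x_t)
}

#' TD weight update
#'
#' `w <- w + alpha * delta * x_t`: the prediction error adjusts the weights
#' of the features active at the earlier step.
#'
#' @param w TD weight vector.
#' @param delta prediction error (finite).
#' @param x_t feature vector active at the step being corrected.
#' @param alpha TD learning rate (> 0).
#' @return the updated weight vector.
#' @export
td_update <- function(w, delta, x_t, alpha = 0.1) {
  if (!is.finite(delta)) stop("delta must be finite", call. = FALSE)
  w + alpha * delta * x_t
}

#' Create a plasticity gating state
#'
#' Large dopamine transients open a gating window during which Hebbian
#' (bursts, `delta > theta_hebb`) or anti-Hebbian (dips,
#' `delta < theta_antihebb`) learning is enabled in the PFC and BG-PMC
#' layers. Burst windows last `min(t_max, ceiling(t_slope * delta))` steps
#' (duration grows with dopamine amplitude, consistent with sub-second
#' dopamine clearance); dip windows last a fixed 15 steps.
#'
#' @param theta_hebb positive burst threshold.
#' @param theta_antihebb negative dip threshold.
#' @param t_max cap on the burst-window length (steps).
#' @param t_slope steps of window per unit of `delta`.
#' @return a `gate_state` list with `mode` ("off"/"hebb"/"antihebb") and
#'   `steps_remaining`.
#' @export
gate_state <- function(theta_hebb = 0.1, theta_antihebb = -0.1,
                       t_max = 10L, t_slope = 10) {
  if (!(theta_antihebb < 0 && 0 < theta_hebb)) {
    stop("need theta_antihebb < 0 < theta_hebb", call. = FALSE)
  }
  structure(
    list(mode = "off", steps_remaining = 0L,
         theta_hebb = theta_hebb, theta_antihebb = theta_antihebb,
         t_max = as.integer(t_max), t_slope = t_slope),
    class = "gate_state"
  )
}

#' Advance the plasticity gate by one step
#'
#' A qualifying prediction error (re)opens a window (the latest event wins,
#' overwriting any open window); otherwise an open window counts down by one
#' step and closes at zero.
#'
#' @param gate a [gate_state()].
#' @param delta the current prediction error.
#' @return the updated `gate_state`.
#' @export
update_gate <- function(gate, delta) {
  if (delta > gate$theta_hebb) {
    gate$mode <- "hebb"
    gate$steps_remaining <- min(gate$t_max,
                                as.integer(ceiling(gate$t_slope * delta)))
  } else if (delta < gate$theta_antihebb) {
    gate$mode <- "antihebb"
    gate$steps_remaining <- 15L
  } else if (gate$steps_remaining > 0L) {
    gate$steps_remaining <- gate$steps_remaining - 1L
    if (gate$steps_remaining == 0L) gate$mode <- "off"
  } else {
    gate$mode <- "off"
  }
  gate
}
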