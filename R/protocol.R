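#' Specify one operant-conditioning trial
#'
#' A trial is a lever-availability period (the conditioned stimulus, CS)
#' followed by an inter-trial interval, all in 100 ms time steps. A press of
#' the correct lever (response R1) terminates the lever-out phase and is
#' rewarded with a pellet one step later.
#'
#' @param steps_lever_out integer; number of steps the lever/CS is available
#'   (>= 1). 600 corresponds to the full 60 s period.
#' @param steps_iti integer; inter-trial steps (>= 0).
#' @param reward_magnitude nonnegative reward delivered on a correct response.
#' @param correct_response index of the rewarded response (default 1, "R1").
#' @return a `trial_spec` object (named list).
#' @examples
#' trial_spec(steps_lever_out = 600, steps_iti = 200)
#' @export
trial_spec <- function(steps_lever_out = 60L, steps_iti = 20L,
                       reward_magnitude = 1, correct_response = 1L) {
  steps_lever_out <- as.integer(steps_lever_out)
  steps_iti <- as.integer(steps_iti)
  if (is.na(steps_lever_out) || steps_lever_out < 1L) {
    stop("steps_lever_out must be an integer >= 1", call. = FALSE)
  }
  if (is.na(steps_iti) || steps_iti < 0L) {
    stop("steps_iti must be an integer >= 0", call. = FALSE)
  }
  if (!is.numeric(reward_magnitude) || reward_magnitude < 0) {
    stop("reward_magnitude must be >= 0", call. = FALSE)
  }
  structure(
    list(steps_lever_out = steps_lever_out, steps_iti = steps_iti,
         reward_magnitude = as.numeric(reward_magnitude),
         correct_response = as.integer(correct_response)),
    class = "trial_spec"
  )
}

#' Build a session of identical trials
#'
#' A training session is an ordered sequence of identical trials (the
#' behavioural protocol used 25-trial sessions).
#'
#' @param spec a [trial_spec()].
#' @param n_trials integer >= 1.
#' @return a tibble with one row per trial (columns `trial`,
#'   `steps_lever_out`, `steps_iti`, `reward_magnitude`, `correct_response`),
#'   class `oc_session`.
#' @examples
#' make_session(trial_spec(), 25)
#' @export
make_session <- function(spec = trial_spec(), n_trials = 25L) {
  if (!inherits(spec, "trial_spec")) stop("spec must be a trial_spec", call. = FALSE)
  n_trials <- as.integer(n_trials)
  if (is.na(n_trials) || n_trials < 1L) {
    stop("n_trials must be an integer >= 1", call. = FALSE)
  }
  out <- tibble::tibble(
    trial            = seq_len(n_trials),
    steps_lever_out  = spec$steps_lever_out,
    steps_iti        = spec$steps_iti,
    reward_magnitude = spec$reward_magnitude,
    correct_response = spec$correct_response
  )
  class(out) <- c("oc_session", class(out))
  out
}

#' Stimulus frame at a given step of a trial
#'
#' Returns the binary conditioned-stimulus (CS, lever out) and
#' unconditioned-stimulus (US, pellet) indicators at step `t` of a trial.
#' The CS is on during the lever-out phase up to and including the response
#' step; the US is on exactly one step after a correct response.
#'
#' @param spec a [trial_spec()].
#' @param t step index, `0 <= t < steps_lever_out + steps_iti`.
#' @param response_step step at which a response occurred, or `NA` if none
#'   (yet).
#' @param correct logical; was the response the rewarded one?
#' @return a named list `list(cs = 0/1, us = 0/1)`.
#' @export
stimulus_at <- function(spec, t, response_step = NA_integer_, correct = FALSE) {
  total <- spec$steps_lever_out + spec$steps_iti
  if (t < 0 || t >= total) {
    stop("step index t out of range [0, ", total - 1L, "]", call. = FALSE)
  }
  cs <- as.integer(t < spec$steps_lever_out &&
                     (is.na(response_step) || t <= response_step))
  us <- as.integer(!is.na(response_step) && isTRUE(correct) &&
                     t == response_step + 1L)
  list(cs = cs, us = us)
}

#' Update a short-term-memory trace
#'
#' Cue-selective input neurons hold a short-term memory (STM) of each
#' stimulus channel: the trace is set to 1 whenever the stimulus is present
#' and decays multiplicatively (factor `lambda`) otherwise, so it always
#' stays in \[0, 1\].
#'
#' @param trace numeric vector of current traces, one per channel.
#' @param present logical/0-1 vector: is each channel's stimulus present?
#' @param lambda decay factor in (0,1).
#' @return the updated trace vector.
#' @examples
#' update_stm(c(0.5, 1), present = c(TRUE, FALSE), lambda = 0.9)
#' @export
update_stm <- function(trace, present, lambda = 0.95) {
  present <- as.logical(present)
  out <- trace * lambda
  out[present] <- 1
  out
}
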