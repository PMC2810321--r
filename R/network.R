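#' Saturating activation
#'
#' Logistic nonlinearity mapping net drive onto \[0, 1\].
#'
#' @param x net drive (vector).
#' @param slope logistic slope.
#' @return activities in \[0, 1\].
#' @keywords internal
sigma_act <- function(x, slope = 4) {
  1 / (1 + exp(-slope * x))
}

#' Winner-take-all masking
#'
#' Keeps the maximum entry (ties broken by lowest index) and zeroes all
#' others, as in the cortical winner-take-all stage.
#'
#' @param activity nonempty numeric vector.
#' @return the masked vector.
#' @examples
#' winner_take_all(c(0.2, 0.9, 0.1))
#' @export
winner_take_all <- function(activity) {
  if (!length(activity)) stop("activity vector must be nonempty", call. = FALSE)
  out <- numeric(length(activity))
  i <- which.max(activity)  # which.max breaks ties by lowest index
  out[i] <- activity[i]
  out
}

#' One step of the prefrontal (PFC) layer
#'
#' Each PFC unit is driven by the stimulus STM traces through its afferent
#' weights plus a baseline; dopamine inhibits all units through a clamped
#' negative VTA weight, while the winning unit (largest drive) receives a
#' D1/NMDA synergism bonus proportional to both dopamine and its
#' glutamatergic afferent drive — so a unit with weak afferents is net
#' inhibited by dopamine but a strongly driven winner is excited. A
#' winner-take-all mask is then applied.
#'
#' @param stm stimulus STM trace vector.
#' @param W_in_pfc afferent weight matrix (`n_pfc` x channels).
#' @param da scalar dopamine signal (the TD prediction error).
#' @param basal_pfc baseline drive.
#' @param w_vta_pfc clamped nonpositive VTA->PFC weight.
#' @param b_winner D1/NMDA synergism gain.
#' @param sigma_slope slope of the saturating nonlinearity.
#' @return `list(activity = masked activity vector, winner = index)`.
#' @export
pfc_step <- function(stm, W_in_pfc, da = 0, basal_pfc = 0,
                     w_vta_pfc = -0.2, b_winner = 0.5, sigma_slope = 4) {
  aff <- as.vector(W_in_pfc %*% stm)
  drive <- aff + w_vta_pfc * da + basal_pfc
  winner <- which.max(drive)
  bonus <- numeric(length(drive))
  bonus[winner] <- b_winner * da * aff[winner]
  act <- sigma_act(drive + bonus, sigma_slope)
  list(activity = winner_take_all(act), winner = winner)
}

#' Tonic locus coeruleus level
#'
#' LC tonic firing falls linearly with the reward rate over a window of
#' recent trials: `lc_max * (1 - mean reward rate)`. An empty history is
#' treated as zero reward (maximal LC drive), so the direct
#' stimulus-response pathway dominates early exploration and fades as the
#' task is mastered.
#'
#' @param reward_window numeric vector of recent per-trial rewards
#'   (interpreted as rates in \[0, 1\]); may be empty.
#' @param lc_max maximal tonic level.
#' @param n_lc number of most recent trials considered.
#' @return scalar in \[0, lc_max\].
#' @export
lc_tonic <- function(reward_window, lc_max = 1, n_lc = 20L) {
  if (!length(reward_window)) return(lc_max)
  recent <- utils::tail(reward_window, n_lc)
  rate <- min(max(mean(recent), 0), 1)
  lc_max * (1 - rate)
}

#' One step of the basal-ganglia/premotor (BG-PMC) response layer
#'
#' Response units integrate the PFC layer through plastic weights and the
#' stimulus STM through a direct pathway whose gain is the tonic LC level.
#' Dopamine applies a "brake" (clamped negative VTA weight) to all motor
#' programmes while the leading unit receives the same afferent-dependent
#' synergism bonus as in the PFC.
#'
#' @param pfc_activity post-WTA PFC activity vector.
#' @param stm stimulus STM trace vector.
#' @param W_pfc_bg weights PFC -> responses (`n_resp` x `n_pfc`).
#' @param W_direct direct weights stimulus -> responses (`n_resp` x channels).
#' @param da scalar dopamine signal.
#' @param lc_level tonic LC level (gain of the direct pathway).
#' @param basal_bgpmc baseline drive of the response units.
#' @param w_vta_bg clamped nonpositive VTA->BG weight.
#' @param b_winner synergism gain (set 0 to disable in this layer).
#' @param sigma_slope slope of the saturating nonlinearity.
#' @param drive_noise additive noise on each unit's net drive (motor
#'   noise; vector of length `n_resp` or 0).
#' @return response activity vector in \[0, 1\].
#' @export
bgpmc_step <- function(pfc_activity, stm, W_pfc_bg, W_direct, da = 0,
                       lc_level = 1, basal_bgpmc = 0, w_vta_bg = -0.2,
                       b_winner = 0.5, sigma_slope = 4, drive_noise = 0) {
  aff <- as.vector(W_pfc_bg %*% pfc_activity) +
    lc_level * as.vector(W_direct %*% stm)
  drive <- aff + w_vta_bg * da + basal_bgpmc + drive_noise
  winner <- which.max(drive)
  bonus <- numeric(length(drive))
  bonus[winner] <- b_winner * da * aff[winner]
  sigma_act(drive + bonus, sigma_slope)
}

#' Select the behavioural response of a trial
#'
#' The first step at which any response unit's activity exceeds the release
#' threshold triggers that response (latency = that step). If no unit ever
#' crosses the threshold during the lever-out phase, a uniformly random
#' response among the `n_resp` alternatives is executed at trial end
#' (`forced = TRUE`, latency = the full lever-out duration).
#'
#' @param z matrix of response activities (steps x `n_resp`) over the
#'   lever-out phase.
#' @param theta_resp release threshold.
#' @param steps_lever_out trial lever-out duration (defaults to `nrow(z)`),
#'   used as the forced-choice latency.
#' @param t_react sensorimotor reaction dead time: no release during the
#'   first `t_react` steps after CS onset.
#' @return `list(response, latency_steps, forced)`.
#' @export
select_response <- function(z, theta_resp = 0.75,
                            steps_lever_out = nrow(z), t_react = 0L) {
  if (!nrow(z)) stop("trial must have at least one step", call. = FALSE)
  crossed <- which(apply(z, 1, max) > theta_resp)
  crossed <- crossed[crossed > t_react]
  if (length(crossed)) {
    t0 <- crossed[1]
    list(response = which.max(z[t0, ]), latency_steps = t0 - 1L,
         forced = FALSE)
  } else {
    list(response = sample.int(ncol(z), 1L),
         latency_steps = as.integer(steps_lever_out), forced = TRUE)
  }
}
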