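#' Run one operant-conditioning model
#'
#' Simulates a single model rat through `n_sessions * trials_per_session`
#' trials, wiring together the trial protocol, the TD dopamine block, the
#' PFC and BG-PMC layers and the gated Hebbian plasticity rule. The run is
#' fully deterministic given `(config, seed)`: the seed controls the initial
#' weights and the uniform 1-in-3 forced responses.
#'
#' @param config an [oc_config()].
#' @param seed integer seed for this model.
#' @return a tibble with one row per trial: `trial`, `session`, `response`,
#'   `correct`, `forced`, `reward`, `latency_steps`, `latency_s`,
#'   `plasticity` (sum of |dW| over the PFC afferent matrix),
#'   `plasticity_all` (including BG-PMC and direct-path synapses),
#'   `lc_level`, and the diagnostic gate counts `hebb_steps` /
#'   `antihebb_steps` (steps per trial with each window open).
#' @examples
#' head(run_model(oc_config(protocol = list(n_sessions = 1)), seed = 1))
#' @export
run_model <- function(config = oc_config(), seed = 1L) {
  if (!inherits(config, "oc_config")) {
    stop("config must be an oc_config object", call. = FALSE)
  }
  withr::with_seed(as.integer(seed), run_model_impl(config))
}

run_model_impl <- function(config) {
  p <- config$protocol; td <- config$td; nw <- config$network
  lp <- config$learning

  n_trials <- p$n_sessions * p$trials_per_session
  slo <- p$steps_lever_out
  iti <- p$steps_iti
  rmag <- p$reward_magnitude
  lam <- p$lambda_stm
  hold <- nw$response_hold_steps
  n_pfc <- nw$n_pfc; n_resp <- nw$n_resp
  n_feat <- slo + 2L

  # state
  w_td <- numeric(n_feat)
  gate <- gate_state(td$theta_hebb, td$theta_antihebb, td$t_max, td$t_slope)
  sc <- nw$init_weight_scale
  W_pfc <- matrix(stats::runif(n_pfc, 0, sc), n_pfc, 1)
  W_bg  <- matrix(stats::runif(n_resp * n_pfc, 0, sc), n_resp, n_pfc)
  W_dir <- matrix(stats::runif(n_resp, 0, sc), n_resp, 1)
  dW_pfc <- matrix(0, n_pfc, 1)
  dW_bg  <- matrix(0, n_resp, n_pfc)
  dW_dir <- matrix(0, n_resp, 1)
  stm_cs <- 0
  stm_resp <- numeric(n_resp)
  reward_hist <- numeric(0)
  b_win_bg <- if (isTRUE(nw$bgpmc_synergism)) nw$b_winner else 0

  out_resp <- integer(n_trials); out_forced <- logical(n_trials)
  out_lat <- integer(n_trials); out_plast <- numeric(n_trials)
  out_plast_all <- numeric(n_trials); out_lc <- numeric(n_trials)
  out_hebb <- integer(n_trials); out_anti <- integer(n_trials)

  for (tr in seq_len(n_trials)) {
    lc <- lc_tonic(reward_hist, nw$lc_max, nw$n_lc)
    responded <- FALSE
    resp <- NA_integer_; t_resp <- NA_integer_; forced <- FALSE
    k_prev <- -1L
    plast <- 0; plast_all <- 0
    n_hebb <- 0L; n_anti <- 0L
    t <- 0L
    t_end <- slo + 1L + iti  # recomputed once a response occurs

    while (t <= t_end) {
      # --- stimulus frame and STM ---
      cs_on <- !responded && t < slo
      stm_cs <- if (cs_on) 1 else stm_cs * lam
      us_on <- responded && !is.na(t_resp) && resp == p$correct_response &&
        t == t_resp + 1L

      # --- forced response at the end of an empty lever-out phase ---
      if (!responded && t == slo) {
        resp <- sample.int(n_resp, 1L)
        t_resp <- t; forced <- TRUE; responded <- TRUE
        t_end <- t_resp + 1L + iti
      }

      # --- serial-compound feature index (one-hot delay line) ---
      in_window <- if (responded) t <= t_resp else t <= slo
      k_cur <- if (in_window) t else -1L

      # --- TD prediction error and update ---
      r_cur <- if (us_on) rmag else 0
      v_cur <- if (k_cur >= 0L && k_cur < n_feat) w_td[k_cur + 1L] else 0
      v_prev <- if (k_prev >= 0L && k_prev < n_feat) w_td[k_prev + 1L] else 0
      delta <- r_cur + td$gamma * v_cur - v_prev
      if (k_prev >= 0L && k_prev < n_feat) {
        w_td[k_prev + 1L] <- w_td[k_prev + 1L] + td$alpha * delta
      }
      gate <- update_gate(gate, delta)
      if (gate$mode == "hebb") n_hebb <- n_hebb + 1L
      if (gate$mode == "antihebb") n_anti <- n_anti + 1L
      da <- delta

      # --- PFC layer ---
      pfc <- pfc_step(stm_cs, W_pfc, da, nw$basal_pfc, nw$w_vta_pfc,
                      nw$b_winner, nw$sigma_slope)
      act_pfc <- pfc$activity

      # --- BG-PMC layer and response release ---
      if (!responded && t >= nw$t_react) {
        eps <- if (nw$noise_sd > 0) {
          stats::rnorm(n_resp, 0, nw$noise_sd)
        } else {
          0
        }
        z <- bgpmc_step(act_pfc, stm_cs, W_bg, W_dir, da, lc,
                        nw$basal_bgpmc, nw$w_vta_bg, b_win_bg,
                        nw$sigma_slope, eps)
        if (max(z) > nw$theta_resp) {
          resp <- which.max(z)
          t_resp <- t; responded <- TRUE
          t_end <- t_resp + 1L + iti
        }
      }

      # --- response execution: activity held at 1 for `hold` steps ---
      resp_active <- logical(n_resp)
      if (responded && t >= t_resp && t < t_resp + hold) {
        resp_active[resp] <- TRUE
      }
      stm_resp <- update_stm(stm_resp, resp_active, lam)

      # --- gated plasticity (momentum decays even with the gate closed) ---
      live <- gate$mode != "off" ||
        max(abs(dW_pfc)) > 1e-12 || max(abs(dW_bg)) > 1e-12 ||
        max(abs(dW_dir)) > 1e-12
      if (live) {
        u1 <- hebbian_update(W_pfc, dW_pfc, stm_cs, act_pfc, gate$mode,
                             lp$mu_pfc, lp$nu_pfc, lp$w_min, lp$w_max)
        W_pfc <- u1$W; dW_pfc <- u1$dW
        u2 <- hebbian_update(W_bg, dW_bg, act_pfc, stm_resp, gate$mode,
                             lp$mu_bgpmc, lp$nu_bgpmc, lp$w_min, lp$w_max)
        W_bg <- u2$W; dW_bg <- u2$dW
        u3 <- hebbian_update(W_dir, dW_dir, stm_cs, stm_resp, gate$mode,
                             lp$mu_bgpmc, lp$nu_bgpmc, lp$w_min, lp$w_max)
        W_dir <- u3$W; dW_dir <- u3$dW
        s1 <- sum(abs(dW_pfc))
        plast <- plast + s1
        plast_all <- plast_all + s1 + sum(abs(dW_bg)) + sum(abs(dW_dir))
      }

      k_prev <- k_cur
      t <- t + 1L
    }

    rewarded <- resp == p$correct_response
    reward_hist <- c(reward_hist, as.numeric(rewarded))
    if (length(reward_hist) > nw$n_lc) {
      reward_hist <- utils::tail(reward_hist, nw$n_lc)
    }
    out_resp[tr] <- resp; out_forced[tr] <- forced
    out_lat[tr] <- t_resp; out_plast[tr] <- plast
    out_plast_all[tr] <- plast_all; out_lc[tr] <- lc
    out_hebb[tr] <- n_hebb; out_anti[tr] <- n_anti
  }

  tibble::tibble(
    trial = seq_len(n_trials),
    session = (seq_len(n_trials) - 1L) %/% p$trials_per_session + 1L,
    response = out_resp,
    correct = out_resp == p$correct_response,
    forced = out_forced,
    reward = as.numeric(out_resp == p$correct_response) * rmag,
    latency_steps = out_lat,
    latency_s = out_lat * 0.1,
    plasticity = out_plast,
    plasticity_all = out_plast_all,
    lc_level = out_lc,
    hebb_steps = out_hebb,
    antihebb_steps = out_anti
  )
}

#' Run an ensemble of models
#'
#' Runs `n_models` independent models (seeds `base_seed .. base_seed +
#' n_models - 1`) and aggregates per-trial performance (fraction of correct
#' responses) and plasticity (sum of |dW|) into mean and standard error of
#' the mean, as reported for the 100-model ensemble.
#'
#' @param config an [oc_config()].
#' @param n_models ensemble size (>= 1).
#' @param base_seed first seed.
#' @return an `oc_trajectory` tibble: `trial`, `mean_perf`, `sem_perf`,
#'   `mean_plast`, `sem_plast`, with attributes `n_models`, `base_seed` and
#'   `config`.
#' @export
run_ensemble <- function(config = oc_config(), n_models = 100L,
                         base_seed = 1L) {
  n_models <- as.integer(n_models)
  if (is.na(n_models) || n_models < 1L) {
    stop("n_models must be an integer >= 1", call. = FALSE)
  }
  seeds <- as.integer(base_seed) + seq_len(n_models) - 1L
  runs <- lapply(seeds, function(s) run_model(config, s))
  perf <- vapply(runs, function(r) as.numeric(r$correct),
                 numeric(nrow(runs[[1]])))
  plast_col <- if (isTRUE(config$learning$include_bgpmc_in_metric)) {
    "plasticity_all"
  } else {
    "plasticity"
  }
  plast <- vapply(runs, function(r) r[[plast_col]], numeric(nrow(runs[[1]])))
  sem <- function(m) {
    if (ncol(m) < 2L) return(numeric(nrow(m)))
    apply(m, 1, stats::sd) / sqrt(ncol(m))
  }
  out <- tibble::tibble(
    trial = runs[[1]]$trial,
    mean_perf = rowMeans(perf),
    sem_perf = sem(perf),
    mean_plast = rowMeans(plast),
    sem_plast = sem(plast)
  )
  attr(out, "n_models") <- n_models
  attr(out, "base_seed") <- as.integer(base_seed)
  attr(out, "config") <- config
  class(out) <- c("oc_trajectory", class(out))
  out
}

#' Binned performance curve
#'
#' Fraction of correct responses per bin of trials (the behavioural
#' sessions had 25 trials each). Forced random responses count as emitted
#' behaviour and are correct only when the rewarded response was drawn, so
#' chance level is 1/3.
#'
#' @param outcomes a per-trial tibble from [run_model()].
#' @param bin_size trials per bin (>= 1).
#' @return a tibble `bin`, `trials`, `frac_correct`.
#' @export
performance_curve <- function(outcomes, bin_size = 25L) {
  bin_size <- as.integer(bin_size)
  if (is.na(bin_size) || bin_size < 1L) {
    stop("bin_size must be an integer >= 1", call. = FALSE)
  }
  outcomes |>
    dplyr::mutate(bin = (.data$trial - 1L) %/% bin_size + 1L) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(trials = dplyr::n(),
                     frac_correct = mean(.data$correct),
                     .groups = "drop")
}

#' Behavioural stage criteria
#'
#' Labels sessions with the two training-stage criteria used for the animal
#' groups: `50%CR` is attained at the first session whose response fraction
#' lies in \[0.50, 0.65\]; `100%CR` at the third consecutive session with a
#' response fraction of 1.0 and mean latency below 5 s.
#'
#' @param session_summaries tibble with columns `session`, `frac_correct`
#'   and `mean_latency_s`.
#' @param latency_criterion_s latency threshold in seconds (default 5).
#' @return the input with logical columns `attained_50cr` / `attained_100cr`
#'   marking the sessions at which each stage is first reached (`FALSE`
#'   everywhere if never reached).
#' @export
stage_criteria <- function(session_summaries, latency_criterion_s = 5) {
  ss <- session_summaries
  need <- c("session", "frac_correct", "mean_latency_s")
  if (!all(need %in% names(ss))) {
    stop("session_summaries needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(ss)
  in50 <- ss$frac_correct >= 0.50 & ss$frac_correct <= 0.65
  attained_50 <- logical(n)
  if (any(in50)) attained_50[which(in50)[1]] <- TRUE
  perfect <- ss$frac_correct >= 1 & ss$mean_latency_s < latency_criterion_s
  streak <- 0L
  attained_100 <- logical(n)
  for (i in seq_len(n)) {
    streak <- if (perfect[i]) streak + 1L else 0L
    if (streak == 3L) {
      attained_100[i] <- TRUE
      break
    }
  }
  ss$attained_50cr <- attained_50
  ss$attained_100cr <- attained_100
  ss
}

#' Centered moving average with partial edge windows
#' @param x numeric vector.
#' @param window odd window size.
#' @return smoothed vector, same length.
#' @keywords internal
smooth_series <- function(x, window = 11L) {
  h <- window %/% 2L
  n <- length(x)
  vapply(seq_len(n),
         function(i) mean(x[max(1L, i - h):min(n, i + h)]),
         numeric(1))
}

#' Windowed ensemble performance at a trial
#'
#' Mean of the ensemble-mean performance over a centered window of trials
#' (single-trial binary outcomes are too noisy to anchor on).
#'
#' @param traj an `oc_trajectory` from [run_ensemble()].
#' @param at center trial.
#' @param window window length in trials.
#' @return scalar fraction correct in \[0, 1\].
#' @export
windowed_performance <- function(traj, at, window = 10L) {
  lo <- at - window %/% 2L
  hi <- lo + window - 1L
  sel <- traj$trial >= lo & traj$trial <= hi
  if (!any(sel)) stop("window [", lo, ",", hi, "] outside trajectory",
                      call. = FALSE)
  mean(traj$mean_perf[sel])
}

#' Trial of peak plasticity
#'
#' The trial at which the smoothed ensemble-mean plasticity trajectory
#' attains its maximum (11-trial centered moving average by default).
#'
#' @param traj an `oc_trajectory`.
#' @param window smoothing window (odd).
#' @return the argmax trial index.
#' @export
plasticity_peak <- function(traj, window = 11L) {
  sm <- smooth_series(traj$mean_plast, window)
  traj$trial[which.max(sm)]
}

#' Scale the plasticity trajectory to an expression anchor
#'
#' Basal transcript levels are not model parameters, so the simulated
#' plasticity trajectory is only defined up to scale; it is anchored by
#' fitting its smoothed value at `anchor_trial` to an experimental value
#' (e.g. the BDNF level of the learning-stage group, 131.9% of control).
#' Ratios along the series are preserved.
#'
#' @param traj an `oc_trajectory`.
#' @param anchor_trial trial at which to pin the series (default 70).
#' @param anchor_value target value at the anchor (percent-of-control scale).
#' @param window smoothing window for the plasticity series.
#' @return `traj` with an added `plast_scaled` column (smoothed, scaled).
#' @export
scale_to_anchor <- function(traj, anchor_trial = 70L, anchor_value,
                            window = 11L) {
  if (!anchor_trial %in% traj$trial) {
    stop("anchor_trial ", anchor_trial, " not in trajectory", call. = FALSE)
  }
  sm <- smooth_series(traj$mean_plast, window)
  ref <- sm[traj$trial == anchor_trial]
  if (!is.finite(ref) || ref <= 0) {
    stop("degenerate anchor: smoothed plasticity at trial ", anchor_trial,
         " is not positive", call. = FALSE)
  }
  traj$plast_scaled <- sm * (anchor_value / ref)
  traj
}

#' Grid-search tuning to the performance anchors
#'
#' The original simulations tuned model parameters so the ensemble reached
#' 65% correct at trial 70 and 100% at trial 120. This helper evaluates a
#' finite grid over the designated tunables (`nu_pfc`, `nu_bgpmc`,
#' `theta_resp`, `theta_hebb`) on a reduced ensemble and returns the grid
#' point minimising the squared deviation from the anchors.
#'
#' @param config base [oc_config()].
#' @param grid data frame whose columns are a subset of
#'   `nu_pfc`, `nu_bgpmc`, `theta_resp`, `theta_hebb`; one row per candidate.
#' @param targets anchor performances (fractions).
#' @param anchor_trials trials at which the anchors apply.
#' @param n_models reduced ensemble size used for evaluation.
#' @param base_seed ensemble base seed.
#' @param window performance window (trials).
#' @return `list(config = best oc_config, report = tibble of grid results)`.
#' @export
tune_parameters <- function(config = oc_config(), grid,
                            targets = c(0.65, 1.00),
                            anchor_trials = c(70L, 120L),
                            n_models = 20L, base_seed = 1L, window = 10L) {
  grid <- as.data.frame(grid)
  if (!nrow(grid)) stop("tuning grid is empty", call. = FALSE)
  allowed <- c("nu_pfc", "nu_bgpmc", "theta_resp", "theta_hebb")
  bad <- setdiff(names(grid), allowed)
  if (length(bad)) {
    stop("non-tunable parameter(s) in grid: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  apply_point <- function(row) {
    lrn <- intersect(names(row), c("nu_pfc", "nu_bgpmc"))
    nw <- intersect(names(row), "theta_resp")
    td <- intersect(names(row), "theta_hebb")
    args <- list()
    if (length(lrn)) args$learning <- as.list(row[lrn])
    if (length(nw)) args$network <- as.list(row[nw])
    if (length(td)) args$td <- as.list(row[td])
    cfg <- config
    for (blk in names(args)) cfg[[blk]][names(args[[blk]])] <- args[[blk]]
    validate_oc_config(cfg)
  }
  losses <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cfg_i <- apply_point(as.list(grid[i, , drop = FALSE]))
    traj <- run_ensemble(cfg_i, n_models = n_models, base_seed = base_seed)
    perf <- vapply(anchor_trials, function(a) {
      windowed_performance(traj, a, window)
    }, numeric(1))
    losses[i] <- sum((perf - targets)^2)
  }
  report <- tibble::as_tibble(grid)
  report$loss <- losses
  best <- which.min(losses)
  list(config = apply_point(as.list(grid[best, , drop = FALSE])),
       report = report[order(report$loss), ])
}
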