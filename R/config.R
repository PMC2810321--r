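#' Build a simulation configuration
#'
#' Assembles the full set of parameters controlling one operant-conditioning
#' simulation: the trial protocol, the temporal-difference (TD) dopamine
#' block, the network layers, and the plasticity rule. Any element can be
#' overridden by name; unknown names are an error. The shipped defaults are
#' the tuned configuration under which a 100-model ensemble reaches about
#' 65% correct around trial 70 and near-perfect performance by trial 120.
#'
#' Time is discretised in 100 ms steps. By default one trial compresses the
#' 60 s lever-availability period to 60 steps (6 s equivalent) and the 20 s
#' inter-trial interval to 20 steps; `faithful = TRUE` restores the full
#' 600/200-step trial.
#'
#' @param ... named overrides, e.g. `td = list(alpha = 0.2)` or
#'   `protocol = list(n_sessions = 3)`. Sub-lists are merged element-wise
#'   into the defaults.
#' @param faithful logical; if `TRUE`, use the uncompressed 600-step
#'   lever-out / 200-step ITI trial.
#' @return an object of class `oc_config`: a named nested list with blocks
#'   `protocol`, `td`, `network`, `learning` and `analysis`.
#' @examples
#' cfg <- oc_config(td = list(alpha = 0.15))
#' cfg$td$alpha
#' @export
oc_config <- function(..., faithful = FALSE) {
  cfg <- list(
    protocol = list(
      n_sessions         = 5L,
      trials_per_session = 25L,
      steps_lever_out    = if (faithful) 600L else 60L,
      steps_iti          = if (faithful) 200L else 20L,
      reward_magnitude   = 1,
      correct_response   = 1L,
      lambda_stm         = 0.95
    ),
    td = list(
      gamma         = 0.81,
      alpha         = 0.02,
      theta_hebb    = 0.3,
      theta_antihebb = -0.1,
      t_max         = 10L,
      t_slope       = 12
    ),
    network = list(
      n_pfc              = 80L,
      n_resp             = 3L,
      basal_pfc          = -0.15,
      basal_bgpmc        = 0,
      b_winner           = 0.5,
      w_vta_pfc          = -0.2,
      w_vta_bg           = -0.2,
      theta_resp         = 0.75,
      t_react            = 4L,
      response_hold_steps = 5L,
      lc_max             = 1,
      n_lc               = 40L,
      sigma_slope        = 4,
      noise_sd           = 0,
      init_weight_scale  = 0.01,
      bgpmc_synergism    = TRUE
    ),
    learning = list(
      mu_pfc   = 0.5,
      mu_bgpmc = 0.5,
      nu_pfc   = 0.01,
      nu_bgpmc = 0.0013,
      w_min    = -1,
      w_max    = 1,
      include_bgpmc_in_metric = FALSE
    ),
    analysis = list(
      perf_window         = 10L,
      plast_smooth_window = 11L
    )
  )
  overrides <- list(...)
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(cfg))
    if (length(bad) || is.null(names(overrides)) || any(names(overrides) == "")) {
      stop("unknown configuration block(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    for (blk in names(overrides)) {
      ov <- overrides[[blk]]
      if (!is.list(ov)) stop("block '", blk, "' must be a named list", call. = FALSE)
      unknown <- setdiff(names(ov), names(cfg[[blk]]))
      if (length(unknown)) {
        stop("unknown field(s) in block '", blk, "': ",
             paste(unknown, collapse = ", "), call. = FALSE)
      }
      cfg[[blk]][names(ov)] <- ov
    }
  }
  validate_oc_config(structure(cfg, class = "oc_config"))
}

#' Read a configuration from a YAML file
#'
#' @param path path to a YAML file whose top-level keys are configuration
#'   blocks (`protocol`, `td`, `network`, `learning`, `analysis`).
#' @return an `oc_config` object (defaults merged with the file's values).
#' @export
read_oc_config <- function(path) {
  if (!file.exists(path)) {
    stop("configuration file not found: ", path, call. = FALSE)
  }
  do.call(oc_config, yaml::read_yaml(path))
}

validate_oc_config <- function(cfg) {
  p <- cfg$protocol; td <- cfg$td; nw <- cfg$network; lp <- cfg$learning
  stopifnot_cfg(p$steps_lever_out >= 1, "protocol$steps_lever_out must be >= 1")
  stopifnot_cfg(p$steps_iti >= 0, "protocol$steps_iti must be >= 0")
  stopifnot_cfg(p$reward_magnitude >= 0, "protocol$reward_magnitude must be >= 0")
  stopifnot_cfg(p$lambda_stm > 0 && p$lambda_stm < 1, "protocol$lambda_stm must be in (0,1)")
  stopifnot_cfg(p$n_sessions >= 1 && p$trials_per_session >= 1,
                "protocol session counts must be >= 1")
  stopifnot_cfg(td$gamma > 0 && td$gamma <= 1, "td$gamma must be in (0,1]")
  stopifnot_cfg(td$alpha > 0, "td$alpha must be > 0")
  stopifnot_cfg(td$theta_hebb > 0, "td$theta_hebb must be > 0")
  stopifnot_cfg(td$theta_antihebb < 0, "td$theta_antihebb must be < 0")
  stopifnot_cfg(td$t_max >= 1 && td$t_slope > 0, "td window map must be positive")
  stopifnot_cfg(nw$w_vta_pfc <= 0 && nw$w_vta_bg <= 0,
                "VTA efferent weights are clamped nonpositive")
  stopifnot_cfg(nw$theta_resp > 0 && nw$theta_resp < 1,
                "network$theta_resp must be in (0,1)")
  stopifnot_cfg(nw$lc_max >= 0 && nw$n_lc >= 1, "LC block invalid")
  stopifnot_cfg(lp$mu_pfc >= 0 && lp$mu_pfc < 1 && lp$mu_bgpmc >= 0 && lp$mu_bgpmc < 1,
                "momentum constants must be in [0,1)")
  stopifnot_cfg(lp$nu_pfc > 0 && lp$nu_bgpmc > 0, "learning rates must be > 0")
  stopifnot_cfg(lp$w_min < lp$w_max, "weight bounds must satisfy w_min < w_max")
  cfg
}

stopifnot_cfg <- function(ok, msg) {
  if (!isTRUE(ok)) stop("invalid configuration: ", msg, call. = FALSE)
  invisible(TRUE)
}

#' @export
print.oc_config <- function(x, ...) {
  cat("<oc_config>\n")
  for (blk in names(x)) {
    cat("  $", blk, ": ", sep = "")
    flds <- vapply(names(x[[blk]]),
                   function(f) paste0(f, "=", format(x[[blk]][[f]])),
                   character(1))
    cat(paste(flds, collapse = ", "), "\n")
  }
  invisible(x)
}
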