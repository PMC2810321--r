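#' Gene and group labels used throughout the expression arm
#' @keywords internal
oc_genes <- c("BDNF", "CREB", "SynapsinI", "CamKII", "cfos", "cjun", "Arc")

#' @keywords internal
oc_groups <- c("Control", "BC50%CR", "50%CR", "BC100%CR", "100%CR")

#' Default effect-size configuration for the synthetic expression generator
#'
#' Group means (percent of the cage-control value) for the seven
#' plasticity-related and immediate-early genes across the five behavioural
#' groups. The three control groups (naive Control and the two box
#' controls) sit at 100. The learning-stage (`50%CR`) means carry the
#' reported increments over their box control (e.g. BDNF +31.9%); the
#' learned-stage (`100%CR`) means carry the reported increments over
#' `BC100%CR` where printed. BDNF's `100%CR` mean is derived from its
#' 18.9% decrease relative to `50%CR` (131.9 x 0.811 = 106.97). Arc's
#' `100%CR` increment was reported only as significant without a
#' percentage; it defaults to 114 (in line with the other IEGs) and can be
#' overridden.
#'
#' @param noise_sd common within-group standard deviation on the
#'   percent-of-control scale (default 9; calibrated so the reported
#'   significance pattern is attainable at n = 6).
#' @param n_per_group replicates per group (default 6 animals).
#' @param arc_100cr mean for Arc in the `100%CR` group (unreported;
#'   default 114).
#' @return an `effect_config` list: `means` (tibble `gene`, `group`,
#'   `mean`), `noise_sd`, `n_per_group`.
#' @examples
#' default_effects()$means
#' @export
default_effects <- function(noise_sd = 9, n_per_group = 6L,
                            arc_100cr = 114) {
  m50 <- c(BDNF = 131.9, CREB = 131, SynapsinI = 127.4, CamKII = 118.7,
           cfos = 126.5, cjun = 129.8, Arc = 130)
  m100 <- c(BDNF = 131.9 * (1 - 0.189), CREB = 114.7, SynapsinI = 116.3,
            CamKII = 115.2, cfos = 114, cjun = 114.2, Arc = arc_100cr)
  means <- tidyr::expand_grid(gene = oc_genes, group = oc_groups) |>
    dplyr::mutate(mean = unname(dplyr::case_when(
      .data$group == "50%CR" ~ m50[.data$gene],
      .data$group == "100%CR" ~ m100[.data$gene],
      TRUE ~ 100
    )))
  effect_config(means, noise_sd = noise_sd, n_per_group = n_per_group)
}

#' Build an effect-size configuration
#'
#' @param means tibble with columns `gene`, `group`, `mean` (all means > 0).
#' @param noise_sd positive common standard deviation (percent scale).
#' @param n_per_group replicates per group (>= 2).
#' @return an `effect_config` object.
#' @export
effect_config <- function(means, noise_sd = 9, n_per_group = 6L) {
  means <- tibble::as_tibble(means)
  if (!all(c("gene", "group", "mean") %in% names(means))) {
    stop("means needs columns gene, group, mean", call. = FALSE)
  }
  bad <- setdiff(unique(means$gene), oc_genes)
  if (length(bad)) {
    stop("unknown gene key(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (any(means$mean <= 0)) stop("all group means must be > 0", call. = FALSE)
  if (!is.numeric(noise_sd) || noise_sd <= 0) {
    stop("noise_sd must be > 0", call. = FALSE)
  }
  n_per_group <- as.integer(n_per_group)
  if (is.na(n_per_group) || n_per_group < 2L) {
    stop("n_per_group must be an integer >= 2", call. = FALSE)
  }
  structure(list(means = means, noise_sd = noise_sd,
                 n_per_group = n_per_group),
            class = "effect_config")
}

#' Generate a synthetic normalized expression table
#'
#' Draws replicate expression values per gene and group from
#' `Normal(group mean, noise_sd)` on the percent-of-control scale,
#' truncated at zero (negative draws are redrawn), emulating beta-actin
#' normalized real-time RT-PCR values expressed as percent of the cage
#' control. Deterministic per seed.
#'
#' @param config an [effect_config()] (default [default_effects()]).
#' @param n_per_group optional override of the configured replicate count.
#' @param seed integer seed.
#' @return a long tibble `gene`, `group`, `replicate`, `value`, class
#'   `oc_expression`.
#' @examples
#' generate_expression(seed = 1) |> head()
#' @export
generate_expression <- function(config = default_effects(),
                                n_per_group = NULL, seed = 1L) {
  if (!inherits(config, "effect_config")) {
    stop("config must be an effect_config", call. = FALSE)
  }
  n <- if (is.null(n_per_group)) config$n_per_group else as.integer(n_per_group)
  if (is.na(n) || n < 2L) stop("n_per_group must be >= 2", call. = FALSE)
  sd <- config$noise_sd
  tab <- withr::with_seed(as.integer(seed), {
    config$means |>
      dplyr::rowwise() |>
      dplyr::mutate(value = list(rnorm_trunc0(n, .data$mean, sd))) |>
      dplyr::ungroup() |>
      dplyr::mutate(replicate = list(seq_len(n))) |>
      tidyr::unnest(c("value", "replicate")) |>
      dplyr::select("gene", "group", "replicate", "value")
  })
  class(tab) <- c("oc_expression", class(tab))
  tab
}

# normal draws truncated at zero by redrawing (vanishingly rare at the
# default means/sd; keeps all values strictly positive)
rnorm_trunc0 <- function(n, mean, sd) {
  x <- stats::rnorm(n, mean, sd)
  while (any(x <= 0)) {
    bad <- x <= 0
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  x
}
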