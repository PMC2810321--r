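#' Normalize an expression table to percent of control
#'
#' Rescales each gene so the mean of the control group maps to exactly 100
#' (the percent-of-cage-control convention): every value is multiplied by
#' `100 / mean(control values)` within its gene. Idempotent on tables whose
#' control mean is already 100.
#'
#' @param data long tibble with columns `gene`, `group`, `value`.
#' @param control_group label of the control group (default "Control").
#' @return the table with `value` rescaled.
#' @export
percent_of_control <- function(data, control_group = "Control") {
  if (!all(c("gene", "group", "value") %in% names(data))) {
    stop("data needs columns gene, group, value", call. = FALSE)
  }
  ctrl <- data |>
    dplyr::filter(.data$group == control_group) |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(ctrl_mean = mean(.data$value), .groups = "drop")
  if (!nrow(ctrl) || any(!is.finite(ctrl$ctrl_mean)) ||
      any(ctrl$ctrl_mean <= 0)) {
    stop("control group '", control_group,
         "' missing or has nonpositive mean", call. = FALSE)
  }
  missing_genes <- setdiff(unique(data$gene), ctrl$gene)
  if (length(missing_genes)) {
    stop("no control values for gene(s): ",
         paste(missing_genes, collapse = ", "), call. = FALSE)
  }
  data |>
    dplyr::left_join(ctrl, by = "gene") |>
    dplyr::mutate(value = .data$value * 100 / .data$ctrl_mean) |>
    dplyr::select(-"ctrl_mean")
}

#' One-way ANOVA
#'
#' Classical one-way analysis of variance across groups (between/within
#' decomposition, F = MSB/MSW), the omnibus test used on each gene before
#' the post hoc comparisons. Degrees of freedom follow N - k for the
#' within term.
#'
#' @param data data frame containing the response and grouping columns.
#' @param value column with the response values (tidy-eval).
#' @param group column with the group labels (tidy-eval).
#' @return an object of class `oc_anova` (wraps the [stats::aov()] fit);
#'   use [generics::tidy()] / [generics::glance()] to extract results.
#' @examples
#' d <- data.frame(v = c(1, 2, 3, 2, 3, 4, 3, 4, 5),
#'                 g = rep(c("a", "b", "c"), each = 3))
#' glance(one_way_anova(d, v, g))
#' @export
one_way_anova <- function(data, value, group) {
  v <- rlang::eval_tidy(rlang::enquo(value), data)
  g <- rlang::eval_tidy(rlang::enquo(group), data)
  g <- factor(g)
  if (nlevels(g) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(table(g) < 2L)) {
    stop("every group needs at least 2 values", call. = FALSE)
  }
  fit <- stats::aov(v ~ g, data = data.frame(v = v, g = g))
  smry <- summary(fit)[[1]]
  structure(
    list(fit = fit,
         F = smry$`F value`[1],
         df_between = smry$Df[1],
         df_within = smry$Df[2],
         p = smry$`Pr(>F)`[1],
         n = length(v), k = nlevels(g)),
    class = "oc_anova"
  )
}

#' @export
print.oc_anova <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.4g, p = %.4g\n",
              x$df_between, x$df_within, x$F, x$p))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an `oc_anova` object
#' @param x an `oc_anova`.
#' @param ... unused.
#' @return a tibble with one row per ANOVA term.
#' @export
tidy.oc_anova <- function(x, ...) {
  smry <- summary(x$fit)[[1]]
  tibble::tibble(
    term = trimws(rownames(smry)),
    df = smry$Df,
    sumsq = smry$`Sum Sq`,
    meansq = smry$`Mean Sq`,
    statistic = smry$`F value`,
    p.value = smry$`Pr(>F)`
  )
}

#' Glance at an `oc_anova` object
#' @param x an `oc_anova`.
#' @param ... unused.
#' @return a one-row tibble: `statistic`, `df_between`, `df_within`,
#'   `p.value`, `n`, `k`.
#' @export
glance.oc_anova <- function(x, ...) {
  tibble::tibble(statistic = x$F, df_between = x$df_between,
                 df_within = x$df_within, p.value = x$p, n = x$n, k = x$k)
}

#' Tukey HSD pairwise comparisons
#'
#' All k(k-1)/2 pairwise group comparisons with studentized-range adjusted
#' p-values (the post hoc test applied after each gene's ANOVA), plus the
#' percent change of each pair computed from the group means.
#'
#' @inheritParams one_way_anova
#' @param alpha significance level for the `significant` flag.
#' @return a tibble: `group_a`, `group_b`, `diff`, `percent_change`
#'   (`100 * (mean_a - mean_b) / mean_b`), `tukey_p`, `significant`.
#' @export
tukey_hsd <- function(data, value, group, alpha = 0.05) {
  v <- rlang::eval_tidy(rlang::enquo(value), data)
  g <- factor(rlang::eval_tidy(rlang::enquo(group), data))
  if (nlevels(g) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(table(g) < 2L)) {
    stop("every group needs at least 2 values", call. = FALSE)
  }
  fit <- stats::aov(v ~ g, data = data.frame(v = v, g = g))
  tk <- stats::TukeyHSD(fit)$g
  pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
  means <- tapply(v, g, mean)
  a <- vapply(pairs, `[`, character(1), 1)
  b <- vapply(pairs, `[`, character(1), 2)
  tibble::tibble(
    group_a = a,
    group_b = b,
    diff = unname(tk[, "diff"]),
    percent_change = as.numeric(100 * (means[a] - means[b]) / means[b]),
    tukey_p = unname(tk[, "p adj"]),
    significant = unname(tk[, "p adj"]) < alpha
  )
}

#' Percent change between two groups
#'
#' `100 * (mean_a - mean_b) / mean_b` of a gene's values, the convention
#' behind statements such as "increased by 31.9% relative to BC50%CR".
#'
#' @param data long tibble with columns `gene`, `group`, `value`.
#' @param gene gene name.
#' @param group_a,group_b group labels (change of `a` relative to `b`).
#' @return scalar percent change.
#' @examples
#' tab <- generate_expression(seed = 7, n_per_group = 200)
#' percent_change(tab, "BDNF", "50%CR", "BC50%CR")
#' @export
percent_change <- function(data, gene, group_a, group_b) {
  d <- data[data$gene == gene, , drop = FALSE]
  if (!nrow(d)) stop("gene '", gene, "' not present", call. = FALSE)
  ma <- mean(d$value[d$group == group_a])
  mb <- mean(d$value[d$group == group_b])
  if (!is.finite(ma) || !is.finite(mb)) {
    stop("group(s) not present for gene '", gene, "'", call. = FALSE)
  }
  if (mb == 0) stop("undefined change: reference mean is zero", call. = FALSE)
  100 * (ma - mb) / mb
}

#' Per-gene ANOVA and Tukey summaries of an expression table
#'
#' Runs the full statistical pipeline — one-way five-group ANOVA followed
#' by Tukey HSD — on every gene of a normalized expression table.
#'
#' @param data long tibble `gene`, `group`, `value`.
#' @return `list(anova = per-gene glance tibble, tukey = per-gene pairwise
#'   tibble)`.
#' @export
expression_stats <- function(data) {
  genes <- unique(data$gene)
  an <- purrr::map_dfr(genes, function(gn) {
    d <- data[data$gene == gn, ]
    dplyr::bind_cols(tibble::tibble(gene = gn),
                     glance(one_way_anova(d, .data$value, .data$group)))
  })
  tk <- purrr::map_dfr(genes, function(gn) {
    d <- data[data$gene == gn, ]
    dplyr::bind_cols(tibble::tibble(gene = gn),
                     tukey_hsd(d, .data$value, .data$group))
  })
  list(anova = an, tukey = tk)
}

#' Compare the scaled plasticity trajectory with a gene's dynamics
#'
#' After [scale_to_anchor()] pins the simulated plasticity series to a
#' gene's learning-stage value, this report compares the scaled series at
#' the learning and learned anchor trials against the gene's measured
#' group values and flags whether the model's decline predicts the
#' transcript's decline within a tolerance.
#'
#' @param scaled_traj trajectory with a `plast_scaled` column (from
#'   [scale_to_anchor()]).
#' @param gene_values named numeric: values (percent of control) at the
#'   learning and learned stage, e.g. `c("50%CR" = 131.9, "100%CR" = 106.97)`.
#' @param trial_learning,trial_learned anchor trials (default 70 and 120).
#' @param tolerance pass tolerance in percentage points (default 10).
#' @return a one-row tibble: model and gene values at both stages, their
#'   percent declines, absolute and relative discrepancies, and `pass`.
#' @export
match_report <- function(scaled_traj, gene_values,
                         trial_learning = 70L, trial_learned = 120L,
                         tolerance = 10) {
  if (!"plast_scaled" %in% names(scaled_traj)) {
    stop("scaled_traj must come from scale_to_anchor()", call. = FALSE)
  }
  if (!all(c(trial_learning, trial_learned) %in% scaled_traj$trial)) {
    stop("anchor trial(s) missing from trajectory", call. = FALSE)
  }
  m70 <- scaled_traj$plast_scaled[scaled_traj$trial == trial_learning]
  m120 <- scaled_traj$plast_scaled[scaled_traj$trial == trial_learned]
  g70 <- gene_values[[1]]
  g120 <- gene_values[[2]]
  model_decline <- 100 * (m70 - m120) / m70
  gene_decline <- 100 * (g70 - g120) / g70
  tibble::tibble(
    trial_learning = trial_learning,
    trial_learned = trial_learned,
    model_learning = m70,
    model_learned = m120,
    gene_learning = g70,
    gene_learned = g120,
    model_decline_pct = model_decline,
    gene_decline_pct = gene_decline,
    abs_discrepancy = abs(model_decline - gene_decline),
    pass = abs(model_decline - gene_decline) <= tolerance
  )
}
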