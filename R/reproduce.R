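#' Reproduce the full analysis end to end
#'
#' One call runs the whole pipeline under a single root seed: the model
#' ensemble (performance and plasticity trajectories), the synthetic
#' expression table, the per-gene ANOVA/Tukey statistics, the BDNF-anchored
#' scaling of the plasticity series and the model-vs-gene match report.
#' All artifacts are written to `out_dir`; reruns with the same inputs
#' produce byte-identical TSVs.
#'
#' Randomness flows from the root seed through fixed named substreams
#' (ensemble seeds `seed .. seed + n_models - 1`; expression seed
#' `seed + 10000`).
#'
#' @param config an [oc_config()] or the path to a YAML configuration.
#' @param seed root integer seed.
#' @param out_dir output directory (created if needed).
#' @param n_models ensemble size.
#' @param make_plots write PDF figures as well.
#' @return an `oc_manifest` list: seeds, output paths, per-stage timings
#'   and headline numbers; also written as `manifest.json`.
#' @export
reproduce <- function(config = oc_config(), seed = 1L, out_dir = "oc-out",
                      n_models = 100L, make_plots = TRUE) {
  if (is.character(config)) config <- read_oc_config(config)
  if (!inherits(config, "oc_config")) {
    stop("config must be an oc_config or a YAML path", call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(seed)
  stage <- function(expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- force(expr)
    list(value = val, secs = round(proc.time()[["elapsed"]] - t0, 2))
  }
  paths <- list()
  timings <- list()

  s1 <- stage(run_ensemble(config, n_models = n_models, base_seed = seed))
  traj <- s1$value; timings$ensemble <- s1$secs
  paths$trajectory <- file.path(out_dir, "trajectory.tsv")
  utils::write.table(as.data.frame(traj), paths$trajectory, sep = "\t",
                     quote = FALSE, row.names = FALSE)

  s2 <- stage(generate_expression(default_effects(), seed = seed + 10000L))
  expr_tab <- s2$value; timings$expression <- s2$secs
  paths$expression <- file.path(out_dir, "expression.tsv")
  utils::write.table(as.data.frame(expr_tab), paths$expression, sep = "\t",
                     quote = FALSE, row.names = FALSE)

  s3 <- stage({
    norm <- percent_of_control(expr_tab)
    st <- expression_stats(norm)
    changes <- tidyr::expand_grid(gene = oc_genes) |>
      dplyr::rowwise() |>
      dplyr::mutate(
        change_50cr = percent_change(norm, .data$gene, "50%CR", "BC50%CR"),
        change_100cr = percent_change(norm, .data$gene, "100%CR", "BC100%CR"),
        change_learned_vs_learning =
          percent_change(norm, .data$gene, "100%CR", "50%CR")
      ) |>
      dplyr::ungroup()
    list(norm = norm, stats = st, changes = changes)
  })
  timings$stats <- s3$secs
  paths$stats <- file.path(out_dir, "stats.json")
  jsonlite::write_json(
    list(anova = s3$value$stats$anova, tukey = s3$value$stats$tukey,
         percent_changes = s3$value$changes),
    paths$stats, digits = NA, auto_unbox = TRUE, dataframe = "rows"
  )

  s4 <- stage({
    bdnf <- s3$value$changes[s3$value$changes$gene == "BDNF", ]
    g70 <- 100 + bdnf$change_50cr
    g120 <- g70 * (1 + bdnf$change_learned_vs_learning / 100)
    scaled <- scale_to_anchor(traj, 70L, g70,
                              config$analysis$plast_smooth_window)
    list(scaled = scaled,
         report = match_report(scaled, c("50%CR" = g70, "100%CR" = g120)))
  })
  timings$match <- s4$secs
  paths$match <- file.path(out_dir, "match.json")
  jsonlite::write_json(s4$value$report, paths$match, digits = NA,
                       auto_unbox = TRUE, dataframe = "rows")

  if (make_plots) {
    s5 <- stage({
      ggplot2::ggsave(file.path(out_dir, "performance.pdf"),
                      autoplot(traj, "performance"), width = 6, height = 4)
      ggplot2::ggsave(file.path(out_dir, "plasticity.pdf"),
                      autoplot(traj, "plasticity"), width = 6, height = 4)
      ggplot2::ggsave(file.path(out_dir, "expression.pdf"),
                      plot_expression(s3$value$norm, s3$value$stats),
                      width = 8, height = 5)
      ggplot2::ggsave(file.path(out_dir, "match.pdf"),
                      plot_match(s4$value$scaled,
                                 c(s4$value$report$gene_learning,
                                   s4$value$report$gene_learned)),
                      width = 6, height = 4)
      TRUE
    })
    timings$plots <- s5$secs
    paths$plots <- file.path(out_dir, c("performance.pdf", "plasticity.pdf",
                                        "expression.pdf", "match.pdf"))
  }

  manifest <- structure(list(
    package_version = as.character(utils::packageVersion("ocplasticity")),
    seed = seed,
    n_models = n_models,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = paths,
    timings_s = timings,
    headline = list(
      perf_trial70 = windowed_performance(traj, 70L,
                                          config$analysis$perf_window),
      perf_trial120 = windowed_performance(traj, 120L,
                                           config$analysis$perf_window),
      plasticity_peak_trial = plasticity_peak(
        traj, config$analysis$plast_smooth_window),
      model_decline_pct = s4$value$report$model_decline_pct,
      gene_decline_pct = s4$value$report$gene_decline_pct
    )
  ), class = "oc_manifest")
  jsonlite::write_json(unclass(manifest), file.path(out_dir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE)
  manifest
}
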