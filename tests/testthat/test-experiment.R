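test_that("runs are deterministic given config and seed", {
  cfg <- quick_config()
  r1 <- run_model(cfg, 7)
  r2 <- run_model(cfg, 7)
  expect_identical(r1, r2)
  r3 <- run_model(cfg, 8)
  expect_false(identical(r1$response, r3$response))
  expect_error(run_model(list(), 1), "oc_config")
})

test_that("with all learning rates effectively zero performance sits at chance", {
  cfg <- oc_config(
    protocol = list(n_sessions = 4L, trials_per_session = 25L,
                    steps_lever_out = 20L, steps_iti = 5L),
    learning = list(nu_pfc = 1e-12, nu_bgpmc = 1e-12)
  )
  correct <- unlist(lapply(1:10, function(s) run_model(cfg, s)$correct))
  # 1000 Bernoulli(1/3) trials: allow ~4 sd around 1/3
  expect_gt(mean(correct), 1 / 3 - 0.06)
  expect_lt(mean(correct), 1 / 3 + 0.06)
})

test_that("default learning increases performance across trial bins", {
  cfg <- oc_config()
  rho <- vapply(1:5, function(s) {
    r <- run_model(cfg, s)
    pc <- performance_curve(r, 25)
    suppressWarnings(stats::cor(pc$bin, pc$frac_correct, method = "spearman"))
  }, numeric(1))
  expect_gt(mean(rho), 0)
})

test_that("performance curves bin fraction correct", {
  out <- tibble::tibble(trial = 1:50,
                        correct = c(rep(TRUE, 15), rep(FALSE, 10),
                                    rep(TRUE, 25)))
  pc <- performance_curve(out, 25)
  expect_equal(pc$frac_correct, c(0.6, 1))
  expect_equal(pc$trials, c(25L, 25L))
  expect_error(performance_curve(out, 0), "bin_size")
})

test_that("ensembles aggregate mean and SEM and shrink SEM like 1/sqrt(n)", {
  cfg <- quick_config()
  t1 <- run_ensemble(cfg, n_models = 1, base_seed = 1)
  expect_true(all(t1$sem_perf == 0))
  expect_true(all(t1$sem_plast == 0))
  t8 <- run_ensemble(cfg, n_models = 8, base_seed = 1)
  expect_true(all(t8$mean_perf >= 0 & t8$mean_perf <= 1))
  expect_true(all(t8$sem_perf >= 0))
  t32 <- run_ensemble(cfg, n_models = 32, base_seed = 1)
  # SEM ratio ~ sqrt(8/32) = 0.5 on average
  ratio <- mean(t32$sem_perf) / mean(t8$sem_perf)
  expect_lt(ratio, 0.85)
  expect_gt(ratio, 0.25)
})

test_that("stage criteria label the behavioural milestones", {
  ss <- tibble::tibble(session = 1:6,
                       frac_correct = c(0.3, 0.55, 0.8, 1, 1, 1),
                       mean_latency_s = c(40, 30, 10, 4, 4, 4))
  lab <- stage_criteria(ss)
  expect_equal(which(lab$attained_50cr), 2L)
  expect_equal(which(lab$attained_100cr), 6L)  # third consecutive perfect

  # high latency blocks the 100%CR criterion
  ss2 <- ss; ss2$mean_latency_s <- rep(10, 6)
  expect_false(any(stage_criteria(ss2)$attained_100cr))

  # never inside [0.50, 0.65]: no 50%CR label
  ss3 <- tibble::tibble(session = 1:3, frac_correct = c(0.2, 0.7, 1),
                        mean_latency_s = c(10, 5, 4))
  expect_false(any(stage_criteria(ss3)$attained_50cr))
  expect_error(stage_criteria(tibble::tibble(session = 1)), "columns")
})

test_that("anchor scaling preserves shape and rescales the anchor trial", {
  traj <- tibble::tibble(trial = 1:125,
                         mean_plast = 0.02 + 0.01 * sin(1:125 / 20) + 0.001,
                         mean_perf = 0.5, sem_perf = 0, sem_plast = 0)
  sc <- scale_to_anchor(traj, 70, 131.9)
  sm <- ocplasticity:::smooth_series(traj$mean_plast, 11)
  expect_equal(sc$plast_scaled[70], 131.9)
  # ratios preserved
  expect_equal(sc$plast_scaled[30] / sc$plast_scaled[90], sm[30] / sm[90])
  # doubling the anchor doubles every point
  sc2 <- scale_to_anchor(traj, 70, 2 * 131.9)
  expect_equal(sc2$plast_scaled, 2 * sc$plast_scaled)
  # identity when the anchor equals the current smoothed value
  sc3 <- scale_to_anchor(traj, 70, sm[70])
  expect_equal(sc3$plast_scaled, sm)

  bad <- traj; bad$mean_plast <- 0
  expect_error(scale_to_anchor(bad, 70, 100), "degenerate anchor")
  expect_error(scale_to_anchor(traj, 999, 100), "not in trajectory")
})

test_that("grid tuning returns the loss-minimising point", {
  cfg <- quick_config()
  expect_error(tune_parameters(cfg, data.frame()), "empty")
  expect_error(tune_parameters(cfg, data.frame(gamma = 1)), "non-tunable")

  single <- tune_parameters(cfg, data.frame(nu_bgpmc = 0.002),
                            n_models = 2, anchor_trials = c(5L, 9L))
  expect_equal(single$config$learning$nu_bgpmc, 0.002)

  grid <- data.frame(nu_bgpmc = c(0.0005, 0.0013, 0.05))
  fit <- tune_parameters(cfg, grid, n_models = 3,
                         anchor_trials = c(5L, 9L))
  expect_equal(nrow(fit$report), 3)
  expect_true(all(diff(fit$report$loss) >= 0))  # sorted ascending
  expect_equal(fit$report$loss[1], min(fit$report$loss))
  expect_true(fit$config$learning$nu_bgpmc %in% grid$nu_bgpmc)
})
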