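test_that("winner-take-all keeps only the maximum with lowest-index ties", {
  expect_equal(winner_take_all(c(0.2, 0.9, 0.1)), c(0, 0.9, 0))
  expect_equal(winner_take_all(c(0.5, 0.5)), c(0.5, 0))
  expect_equal(winner_take_all(c(0, 0, 0)), c(0, 0, 0))
  expect_error(winner_take_all(numeric(0)), "nonempty")
})

test_that("PFC units show dopamine inhibition and afferent-gated synergism", {
  W0 <- matrix(0, 4, 1)
  base <- pfc_step(1, W0, da = 0, basal_pfc = 0.2)
  expect_equal(base$winner, 1L)  # degenerate tie -> lowest index
  expect_true(all(base$activity >= 0 & base$activity <= 1))

  # dopamine with no afferent drive inhibits every unit, winner included
  inhib <- pfc_step(1, W0, da = 1, basal_pfc = 0.2)
  expect_lt(max(inhib$activity), max(base$activity))

  # strong afferent drive on one unit plus dopamine exceeds its da=0 level
  W <- matrix(c(1, 0, 0, 0), 4, 1)
  on <- pfc_step(1, W, da = 1, b_winner = 0.5, basal_pfc = 0)
  off <- pfc_step(1, W, da = 0, b_winner = 0.5, basal_pfc = 0)
  expect_equal(on$winner, 1L)
  expect_gt(on$activity[1], off$activity[1])
})

test_that("dopamine has no effect when its pathways are ablated", {
  withr::with_seed(11, {
    W <- matrix(runif(6, -0.5, 0.5), 6, 1)
    a0 <- pfc_step(0.7, W, da = 0, w_vta_pfc = 0, b_winner = 0)
    a1 <- pfc_step(0.7, W, da = 5, w_vta_pfc = 0, b_winner = 0)
    expect_equal(a0$activity, a1$activity)
    Wbg <- matrix(runif(18, -0.5, 0.5), 3, 6)
    Wd <- matrix(runif(3), 3, 1)
    z0 <- bgpmc_step(a0$activity, 0.7, Wbg, Wd, da = 0, w_vta_bg = 0,
                     b_winner = 0)
    z1 <- bgpmc_step(a0$activity, 0.7, Wbg, Wd, da = 5, w_vta_bg = 0,
                     b_winner = 0)
    expect_equal(z0, z1)
  })
})

test_that("activities stay in [0,1] for arbitrary bounded weights", {
  withr::with_seed(3, {
    for (rep in 1:25) {
      W <- matrix(runif(8, -1, 1), 8, 1)
      Wbg <- matrix(runif(24, -1, 1), 3, 8)
      Wd <- matrix(runif(3, -1, 1), 3, 1)
      stm <- runif(1)
      da <- rnorm(1)
      p <- pfc_step(stm, W, da)
      z <- bgpmc_step(p$activity, stm, Wbg, Wd, da, lc_level = runif(1))
      expect_true(all(p$activity >= 0 & p$activity <= 1))
      expect_true(all(z >= 0 & z <= 1))
    }
  })
})

test_that("the dopamine brake lowers response activities", {
  Wbg <- matrix(0, 3, 2)
  Wd <- matrix(0, 3, 1)
  z0 <- bgpmc_step(c(0, 0), 1, Wbg, Wd, da = 0, basal_bgpmc = 0.3)
  z1 <- bgpmc_step(c(0, 0), 1, Wbg, Wd, da = 1, basal_bgpmc = 0.3)
  expect_true(all(z1 < z0))
  # LC at zero silences the direct pathway
  Wd2 <- matrix(c(5, 0, 0), 3, 1)
  zlc0 <- bgpmc_step(c(0, 0), 1, Wbg, Wd2, lc_level = 0)
  zref <- bgpmc_step(c(0, 0), 1, Wbg, Wd, lc_level = 0)
  expect_equal(zlc0, zref)
})

test_that("tonic LC level decreases linearly with the reward rate", {
  expect_equal(lc_tonic(rep(1, 10), lc_max = 1, n_lc = 10), 0)
  expect_equal(lc_tonic(rep(0, 10), lc_max = 1, n_lc = 10), 1)
  expect_equal(lc_tonic(c(rep(1, 5), rep(0, 5)), 1, 10), 0.5)
  expect_equal(lc_tonic(numeric(0), lc_max = 0.8), 0.8)
  # only the last n_lc trials count
  expect_equal(lc_tonic(c(rep(0, 50), rep(1, 10)), 1, 10), 0)
})

test_that("responses release at the first threshold crossing", {
  z <- matrix(0.1, nrow = 12, ncol = 3)
  z[8, 1] <- 0.9  # step index 8 -> latency 7 (0-based)
  sel <- select_response(z, theta_resp = 0.75)
  expect_equal(sel$response, 1L)
  expect_equal(sel$latency_steps, 7L)
  expect_false(sel$forced)

  # the reaction dead time postpones an early crossing
  z2 <- matrix(0.1, nrow = 12, ncol = 3)
  z2[2, 2] <- 0.9; z2[9, 3] <- 0.9
  sel2 <- select_response(z2, 0.75, t_react = 4)
  expect_equal(sel2$response, 3L)
  expect_equal(sel2$latency_steps, 8L)
})

test_that("forced choices are uniform over the three responses", {
  z <- matrix(0.1, nrow = 5, ncol = 3)  # never crosses
  n <- 9000
  picks <- withr::with_seed(123, {
    vapply(seq_len(n), function(i) {
      s <- select_response(z, theta_resp = 0.75, steps_lever_out = 60)
      stopifnot(s$forced, s$latency_steps == 60L)
      s$response
    }, integer(1))
  })
  freq <- tabulate(picks, 3) / n
  expect_true(all(abs(freq - 1 / 3) < 0.02))
  # chi-square goodness of fit not rejected at alpha = 0.01
  expect_gt(stats::chisq.test(tabulate(picks, 3))$p.value, 0.01)
})
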