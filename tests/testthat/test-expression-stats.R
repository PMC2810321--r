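test_that("percent-of-control normalization pins the control mean at 100", {
  tab <- tibble::tibble(
    gene = "BDNF",
    group = rep(c("Control", "50%CR"), each = 3),
    value = c(2, 2, 2, 4, 4, 4)
  )
  norm <- percent_of_control(tab)
  expect_equal(mean(norm$value[norm$group == "Control"]), 100)
  expect_equal(norm$value[norm$group == "50%CR"], rep(200, 3))
  # idempotent on an already-normalized table
  expect_equal(percent_of_control(norm)$value, norm$value)
  expect_error(percent_of_control(dplyr::filter(tab, group != "Control")),
               "missing|control")
})

test_that("one-way ANOVA reproduces the hand-computed decomposition", {
  d <- data.frame(v = c(1, 2, 3, 2, 3, 4, 3, 4, 5),
                  g = rep(c("a", "b", "c"), each = 3))
  fit <- one_way_anova(d, v, g)
  # oracle by hand: SSB = 6, SSW = 6, MSB = 3, MSW = 1 -> F = 3 exactly
  expect_equal(fit$F, 3)
  expect_equal(fit$df_between, 2)
  expect_equal(fit$df_within, 6)
  expect_equal(fit$p, 1 - stats::pf(3, 2, 6))

  td <- tidy(fit)
  expect_equal(td$sumsq, c(6, 6))
  expect_equal(td$meansq, c(3, 1))
  gl <- glance(fit)
  expect_equal(gl$statistic, 3)

  # identical groups: F = 0
  same <- data.frame(v = rep(c(1, 2, 3), 3), g = rep(c("a", "b", "c"), each = 3))
  expect_equal(one_way_anova(same, v, g)$F, 0)

  # the study design: 5 groups x 6 replicates -> df (4, 25) as N - k
  tab <- generate_expression(seed = 2)
  bdnf <- tab[tab$gene == "BDNF", ]
  f5 <- one_way_anova(bdnf, value, group)
  expect_equal(f5$df_between, 4)
  expect_equal(f5$df_within, 25)

  expect_error(one_way_anova(data.frame(v = 1:3, g = c("a", "a", "b")), v, g),
               "at least 2")
})

test_that("F-test p agrees with a brute-force permutation null on a small table", {
  withr::with_seed(2, {
    d <- data.frame(v = rnorm(18, rep(c(0, 0.6, 1.2), each = 6)),
                    g = rep(c("a", "b", "c"), each = 6))
  })
  fit <- one_way_anova(d, v, g)
  fstat <- function(v, g) {
    m <- tapply(v, g, mean); n <- 6
    ssb <- sum(n * (m - mean(v))^2)
    ssw <- sum((v - m[g])^2)
    (ssb / 2) / (ssw / 15)
  }
  perm <- withr::with_seed(99, {
    vapply(1:20000, function(i) fstat(sample(d$v), d$g), numeric(1))
  })
  p_perm <- mean(perm >= fit$F - 1e-12)
  expect_lt(abs(p_perm - fit$p), 0.02)
})

test_that("Tukey HSD reports all pairs with sensible significance calls", {
  tab <- generate_expression(seed = 6)
  bdnf <- tab[tab$gene == "BDNF", ]
  tk <- tukey_hsd(bdnf, value, group)
  expect_equal(nrow(tk), 10)  # choose(5, 2)
  expect_true(all(tk$tukey_p >= 0 & tk$tukey_p <= 1))

  # identical groups: nothing significant
  withr::with_seed(8, {
    same <- data.frame(v = rnorm(30), g = rep(letters[1:5], each = 6))
  })
  expect_false(any(tukey_hsd(same, v, g)$significant))

  # one group shifted far beyond noise: all its pairs significant
  withr::with_seed(9, {
    shifted <- data.frame(v = c(rnorm(6, 100), rnorm(6)),
                          g = rep(c("hi", "lo"), each = 6))
  })
  expect_true(all(tukey_hsd(shifted, v, g)$significant))
})

test_that("percent changes recover the configured effects", {
  tab <- tibble::tibble(gene = "BDNF",
                        group = rep(c("BC50%CR", "50%CR"), each = 2),
                        value = c(100, 100, 131.9, 131.9))
  expect_equal(percent_change(tab, "BDNF", "50%CR", "BC50%CR"), 31.9)
  expect_equal(percent_change(tab, "BDNF", "50%CR", "50%CR"), 0)
  tab2 <- tibble::tibble(gene = "BDNF",
                         group = rep(c("50%CR", "100%CR"), each = 1),
                         value = c(131.9, 131.9 * 0.811))
  expect_equal(percent_change(tab2, "BDNF", "100%CR", "50%CR"), -18.9)
  expect_error(percent_change(tab, "NOPE", "50%CR", "BC50%CR"), "not present")
  zero <- tibble::tibble(gene = "BDNF", group = c("a", "b"), value = c(1, 0))
  expect_error(percent_change(zero, "BDNF", "a", "b"), "zero")
})

test_that("large-sample percent changes recover every printed effect within 1", {
  tab <- generate_expression(n_per_group = 10000, seed = 7) |>
    percent_of_control()
  expected_50 <- c(BDNF = 31.9, CREB = 31, SynapsinI = 27.4, CamKII = 18.7,
                   cfos = 26.5, cjun = 29.8, Arc = 30)
  for (g in names(expected_50)) {
    expect_equal(percent_change(tab, g, "50%CR", "BC50%CR"),
                 expected_50[[g]], tolerance = 1 / expected_50[[g]])
  }
  expect_equal(percent_change(tab, "BDNF", "100%CR", "50%CR"), -18.9,
               tolerance = 1 / 18.9)
})

test_that("the modal Tukey pattern matches the reported significance calls", {
  # at n = 6 and noise_sd = 9, the learning-stage increase should be
  # detected for every gene in most replicates, and control-control
  # comparisons should almost never fire
  n_rep <- 500
  genes <- unique(default_effects()$means$gene)
  hit_50 <- matrix(FALSE, n_rep, length(genes),
                   dimnames = list(NULL, genes))
  ctrl_fire <- logical(n_rep)
  ctrl_pairs <- c("Control", "BC50%CR", "BC100%CR")
  for (i in seq_len(n_rep)) {
    tab <- generate_expression(seed = 5000 + i)
    any_ctrl <- FALSE
    for (g in genes) {
      tk <- tukey_hsd(tab[tab$gene == g, ], value, group)
      key <- (tk$group_a == "50%CR" & tk$group_b == "BC50%CR") |
        (tk$group_a == "BC50%CR" & tk$group_b == "50%CR")
      hit_50[i, g] <- tk$significant[key]
      cc <- tk$group_a %in% ctrl_pairs & tk$group_b %in% ctrl_pairs
      any_ctrl <- any_ctrl || any(tk$significant[cc])
    }
    ctrl_fire[i] <- any_ctrl
  }
  expect_true(all(colMeans(hit_50) >= 0.5))
  expect_lt(mean(ctrl_fire), 0.5)
})

test_that("match reports compare scaled plasticity with gene dynamics", {
  traj <- tibble::tibble(trial = 1:125, mean_plast = 1, mean_perf = 1,
                         sem_perf = 0, sem_plast = 0)
  traj$mean_plast <- 0.05 - 0.0002 * abs(80 - traj$trial)
  sc <- scale_to_anchor(traj, 70, 131.9)
  rep <- match_report(sc, c("50%CR" = 131.9, "100%CR" = 106.97))
  expect_equal(rep$model_learning, 131.9)
  expect_equal(rep$gene_decline_pct, 100 * (131.9 - 106.97) / 131.9)
  # a flat series fails at the default tolerance
  flat <- sc; flat$plast_scaled <- rep(131.9, 125)
  rflat <- match_report(flat, c("50%CR" = 131.9, "100%CR" = 106.97))
  expect_equal(rflat$model_decline_pct, 0)
  expect_false(rflat$pass)
  # a series matching the gene exactly passes with zero discrepancy
  exact <- sc
  exact$plast_scaled <- seq(131.9, 106.97,
                            length.out = 51)[pmin(pmax(exact$trial - 69, 1), 51)]
  rex <- match_report(exact, c("50%CR" = 131.9, "100%CR" = 106.97))
  expect_equal(rex$abs_discrepancy, 0, tolerance = 1e-10)
  expect_true(rex$pass)
  expect_error(match_report(traj, c(1, 2)), "scale_to_anchor")
})
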