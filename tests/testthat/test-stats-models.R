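test_that("standardized OLS recovers exact and null relationships", {
  x <- rnorm(100)
  tab <- data.frame(x = x, y = 2 * x)
  fit <- suppressWarnings(fitOLSStandardized(tab, "y", "x"))  # perfect fit
  bx <- fit$terms[fit$terms$term == "x", ]
  expect_equal(bx$beta, 1.0, tolerance = 1e-10)
  expect_lt(bx$p, 1e-12)

  ## null coverage: |beta| < 2 SE in about 95% of replicates
  set.seed(100)
  cover <- mean(replicate(200, {
    tabn <- data.frame(x = rnorm(150), y = rnorm(150))
    f <- fitOLSStandardized(tabn, "y", "x")
    b <- f$terms[f$terms$term == "x", ]
    abs(b$beta) < 2 * b$se
  }))
  expect_gt(cover, 0.90)
  expect_lte(cover, 1.0)
})

test_that("standardized fits are invariant to positive rescaling of inputs", {
  set.seed(101)
  tab <- data.frame(x = rnorm(200), z = rnorm(200))
  tab$y <- 0.4 * tab$x - 0.2 * tab$z + rnorm(200)
  f1 <- fitOLSStandardized(tab, "y", "x", "z")
  tab2 <- tab
  tab2$x <- tab2$x * 1000
  tab2$y <- tab2$y / 37
  f2 <- fitOLSStandardized(tab2, "y", "x", "z")
  expect_equal(f1$terms$beta, f2$terms$beta, tolerance = 1e-10)
  expect_equal(f1$terms$p, f2$terms$p, tolerance = 1e-10)
})

test_that("OLS guards rank deficiency, missing columns, and listwise deletion", {
  set.seed(102)
  tab <- data.frame(x = rnorm(50))
  tab$y <- tab$x + rnorm(50)
  tab$x2 <- tab$x
  expect_error(fitOLSStandardized(tab, "y", "x", "x2"), "aliased")
  expect_error(fitOLSStandardized(tab, "y", "nope"), "nope")
  expect_error(fitOLSStandardized(tab, "y", "x", "x"), "must not appear")
  tab$x[1:5] <- NA
  f <- fitOLSStandardized(tab[, c("x", "y")], "y", "x")
  expect_equal(f$n_used, 45L)
})

test_that("Sobel test matches its closed form", {
  s0 <- sobelTest(0, 0.1, 0.4, 0.1)
  expect_equal(s0$z, 0)
  expect_equal(s0$p, 1)
  s <- sobelTest(0.5, 0.1, 0.4, 0.1)
  expect_equal(s$z, 0.2 / sqrt(0.0041), tolerance = 1e-12)
  expect_equal(s$p, 2 * pnorm(-abs(s$z)), tolerance = 1e-12)
  expect_equal(sign(sobelTest(-0.3, 0.1, 0.4, 0.1)$z), -1)
  expect_equal(sign(sobelTest(-0.3, 0.1, -0.4, 0.1)$z), 1)
  expect_error(sobelTest(0.1, 0, 0.2, 0.1), "positive")
})

covars <- c("income_bracket", "age_months", "togetherness")

test_that("mediation classification recovers planted structures", {
  ## partial mediation: a < 0, b > 0, c' < 0
  cfg <- cohortConfig(n_subjects = 2000L, seed = 111L)
  sim <- simulateCohort(cfg, mode = "matrix")
  med <- runMediation(sim$cohort, "god_first_family_second", "mediator",
                      "flanker", covars)
  expect_identical(med$mediation_class, "partial")
  expect_lt(med$sobel_p, 0.05)
  expect_lt(med$a, 0)
  expect_gt(med$b, 0)
  expect_lt(med$c_prime, 0)
  expect_equal(med$indirect_ab, med$a * med$b)

  ## full mediation: c' = 0, a and b nonzero
  cfg_f <- cohortConfig(n_subjects = 2000L, path_cprime_effect = 0,
                        moderation_effect = 0, seed = 112L)
  sim_f <- simulateCohort(cfg_f, mode = "matrix")
  med_f <- runMediation(sim_f$cohort, "god_first_family_second", "mediator",
                        "flanker", covars)
  expect_identical(med_f$mediation_class, "full")

  ## no mediation: a = 0
  cfg_0 <- cohortConfig(n_subjects = 2000L, path_a_effect = 0,
                        moderation_effect = 0, seed = 113L)
  sim_0 <- simulateCohort(cfg_0, mode = "matrix")
  med_0 <- runMediation(sim_0$cohort, "god_first_family_second", "mediator",
                        "flanker", covars)
  expect_identical(med_0$mediation_class, "none")
})

test_that("Sobel agrees with a nonparametric bootstrap of the indirect effect", {
  cfg <- cohortConfig(n_subjects = 300L, path_a_effect = -0.3,
                      path_b_effect = 0.3, seed = 114L)
  sim <- simulateCohort(cfg, mode = "matrix")
  tab <- sim$cohort
  med <- runMediation(tab, "god_first_family_second", "mediator", "flanker")
  set.seed(999)
  zb <- as.numeric(scale(tab$god_first_family_second))
  zm <- as.numeric(scale(tab$mediator))
  zy <- as.numeric(scale(tab$flanker))
  boots <- replicate(1000, {
    i <- sample.int(nrow(tab), replace = TRUE)
    a <- coef(lm(zm[i] ~ zb[i]))[2]
    b <- coef(lm(zy[i] ~ zb[i] + zm[i]))[3]
    a * b
  })
  ci <- quantile(boots, c(0.025, 0.975))
  boot_sig <- ci[1] > 0 || ci[2] < 0
  expect_identical(sign(median(boots)), sign(med$indirect_ab))
  expect_identical(boot_sig, med$sobel_p < 0.05)
})

test_that("moderation recovers null and planted interactions with simple slopes", {
  cfg0 <- cohortConfig(n_subjects = 2000L, moderation_effect = 0, seed = 115L)
  sim0 <- simulateCohort(cfg0, mode = "matrix")
  mod0 <- runModeration(sim0$cohort, "mediator", "flanker",
                        "god_first_family_second", covars)
  expect_lt(mod0$f_squared, 0.01)
  s0 <- mod0$simple_slopes
  ref <- s0$slope[s0$level == 1]
  for (l in s0$level[-1]) {
    row <- s0[s0$level == l, ]
    expect_lt(abs(row$slope - ref), 2 * sqrt(row$se^2 + s0$se[1]^2) + 0.02)
  }

  cfg1 <- cohortConfig(n_subjects = 2000L, moderation_effect = -0.15,
                       seed = 116L)
  sim1 <- simulateCohort(cfg1, mode = "matrix")
  mod1 <- runModeration(sim1$cohort, "mediator", "flanker",
                        "god_first_family_second", covars)
  s1 <- mod1$simple_slopes
  expect_lt(s1$slope[s1$level == 5], s1$slope[s1$level == 1])
  expect_lt(mod1$interaction_p, 0.05)
  ## f^2 consistency with the returned R^2 pair
  expect_equal(mod1$f_squared,
               (mod1$r2_full - mod1$r2_reduced) / (1 - mod1$r2_full),
               tolerance = 1e-12)
  expect_gte(mod1$f_squared, 0)
})

test_that("Cohen's d uses the df-weighted pooled SD", {
  g <- c(0, 1, -1)
  expect_equal(cohensD(g, g)$d, 0)
  expect_equal(cohensD(g, g + 1)$d, 1.0)
  set.seed(117)
  g1 <- rnorm(100, 0, 1); g2 <- rnorm(400, 0.25, 1.2)
  res <- cohensD(g1, g2)
  sp <- sqrt((99 * var(g1) + 399 * var(g2)) / 498)
  expect_equal(res$d, (mean(g2) - mean(g1)) / sp, tolerance = 1e-12)
  expect_lt(res$ci[1], res$d)
  expect_gt(res$ci[2], res$d)
  expect_error(cohensD(rep(1, 5), rep(1, 5)), "pooled variance")
})

test_that("FDR adjustment reproduces step-up arithmetic and BY dominance", {
  expect_equal(fdrAdjust(0.03), 0.03)
  p <- c(0.01, 0.02, 0.03, 0.04)
  bh <- fdrAdjust(p, "independent_BH")
  expect_equal(bh, rep(0.04, 4), tolerance = 1e-12)
  expect_true(all(bh <= 0.05))
  by <- fdrAdjust(p, "dependent_BY")
  expect_true(all(by >= bh - 1e-15))
  expect_equal(by, bh * sum(1 / (1:4)), tolerance = 1e-12)
  expect_error(fdrAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("site propensity adjustment reflects the separability of sites", {
  cfg <- cohortConfig(n_subjects = 1200L, n_sites = 4L, seed = 118L)
  rec <- generateCovariates(cfg)
  out <- siteAdjustment(rec, "site", c("age_months", "income_bracket", "bmi"))
  expect_true(all(out$site_propensity > 0 & out$site_propensity < 1))
  ## sites assigned independently of demographics: probabilities near 1/4
  expect_lt(max(abs(out$site_propensity - 0.25)), 0.15)

  ## fully separable assignment: own-site probabilities near 1
  rec2 <- rec
  rec2$site <- ifelse(rec2$income_bracket <= 3, "siteA", "siteB")
  out2 <- siteAdjustment(rec2, "site", "income_bracket")
  expect_gt(mean(out2$site_propensity), 0.95)

  out3 <- siteAdjustment(rec, "site", "age_months", variant = "ipw")
  expect_true(all(out3$site_ipw >= 1))
  expect_warning(siteAdjustment(rec[1:30, ], "site", "age_months"),
                 "fewer than")
})

test_that("split-sample validation is exact on perfect data and deterministic", {
  set.seed(119)
  tab <- data.frame(x1 = rnorm(400), x2 = rnorm(400))
  tab$y <- 5 + 2 * tab$x1 - tab$x2
  v <- splitSampleValidate(tab, "y", c("x1", "x2"), n_repeats = 20, seed = 3)
  expect_true(all(abs(v$per_repeat$cv_rmse) < 1e-10))
  expect_equal(v$n_train + v$n_test, 400L)

  tab$y <- tab$y + rnorm(400, sd = 0.5)
  v1 <- splitSampleValidate(tab, "y", c("x1", "x2"), n_repeats = 15, seed = 7)
  v2 <- splitSampleValidate(tab, "y", c("x1", "x2"), n_repeats = 15, seed = 7)
  expect_identical(v1$per_repeat, v2$per_repeat)
  expect_gt(v1$median_cv_rmse, 0)

  ## near-zero outcome mean yields flagged undefined repeats
  tab$y0 <- rnorm(400, 0, 1)
  v0 <- splitSampleValidate(tab, "y0", c("x1", "x2"), n_repeats = 5, seed = 1,
                            normalizer = "range")
  expect_equal(v0$n_undefined, 0L)
})
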