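test_that("velocity-ratio transform matches analytic values", {
  expect_equal(transform_vr(0.25), log(pi / 6))
  expect_equal(transform_vr(1 - 1e-12), log(pi / 2), tolerance = 1e-5)
  expect_equal(transform_vr(0.276), -0.5921537, tolerance = 1e-6)
  expect_error(transform_vr(0), "inside")
  expect_error(transform_vr(1), "inside")
})

test_that("published model reproduces the printed test-set probabilities", {
  m <- published_feeding_model()
  expect_equal(predict(m, 0.199)$p_worm, 0.365, tolerance = 0.005)
  expect_equal(predict(m, 0.458)$p_worm, 0.660, tolerance = 0.005)
  expect_equal(predict(m, 0.478)$p_worm, 0.675, tolerance = 0.005)

  t8 <- load_fixture("T8")
  pr <- predict(m, t8$VR)
  dev <- abs(pr$p_worm - t8$p_hat)
  expect_true(all(dev <= 0.01))
  expect_gte(sum(dev <= 0.005), 28)
  # the flagged internally inconsistent row(s) are the only ones beyond 0.005
  expect_true(all(t8$flag_inconsistent[dev > 0.005] == 1))
  # habit calls reproduce the printed predicted feeding type everywhere
  expect_equal(pr$habit_call, t8$predicted)
})

test_that("prediction is strictly increasing in VR under a positive slope", {
  m <- published_feeding_model()
  vr <- seq(0.01, 0.99, by = 0.01)
  expect_true(all(diff(predict(m, vr)$p_worm) > 0))
})

test_that("probability and velocity-ratio thresholds are one cut", {
  m <- published_feeding_model()
  vrstar <- threshold_from_p(m, 0.475)
  expect_lt(abs(vrstar - 0.276), 0.002)

  # construction: p at t = log(pi/4) maps back to VR = 0.5 exactly
  p_half <- stats::plogis(m$intercept + m$slope * log(pi / 4))
  expect_equal(threshold_from_p(m, p_half), 0.5)

  ps <- seq(0.05, 0.9, by = 0.05)
  expect_true(all(diff(threshold_from_p(m, ps)) > 0))   # monotone

  # classify-by-p agrees with classify-by-VR when the cuts correspond
  m2 <- feeding_model(0.8, 1.9, threshold_p = 0.4, threshold_vr = 0.5)
  m2$threshold_vr <- threshold_from_p(m2, 0.4)
  vr <- seq(0.02, 0.98, by = 0.004)
  pr <- predict(m2, vr)
  expect_equal(pr$habit_call == "microarthropod", pr$p_worm < 0.4)

  expect_error(threshold_from_p(m, 1), "in \\(0, 1\\)")
  expect_error(threshold_from_p(m, 0.999999), "arcsine")
})

test_that("likelihood fitter agrees with a brute-force Newton oracle", {
  set.seed(21)
  for (i in 1:8) {
    n <- sample(10:30, 1)
    vr <- runif(n, 0.05, 0.9)
    y <- rbinom(n, 1, plogis(1 + 2 * transform_vr(vr)))
    if (length(unique(y)) < 2 || sum(y) < 2 || sum(1 - y) < 2) next
    m <- suppressWarnings(fit_feeding_model(vr, y))
    if (m$fit_report$separation) next
    beta <- logit_newton_oracle(transform_vr(vr), y)
    expect_equal(m$intercept, beta[1], tolerance = 1e-6)
    expect_equal(m$slope, beta[2], tolerance = 1e-6)
  }
})

test_that("refitting recovers generator coefficients at nominal coverage", {
  hits0 <- 0; hits1 <- 0
  for (seed in 1:100) {
    set.seed(seed)
    vr <- runif(2000, 0.08, 0.85)
    y <- rbinom(2000, 1, plogis(1.4 + 2.6 * transform_vr(vr)))
    m <- fit_feeding_model(vr, y)
    se <- m$fit_report$se
    if (abs(m$intercept - 1.4) <= 1.96 * se[1]) hits0 <- hits0 + 1
    if (abs(m$slope - 2.6) <= 1.96 * se[2]) hits1 <- hits1 + 1
  }
  expect_gte(hits0, 90)
  expect_gte(hits1, 90)
})

test_that("mixed-diet species enter the fit once per prey class", {
  vr <- c(0.1, 0.15, 0.55, 0.6, 0.3, 0.35)
  lab <- c("microarthropod", "microarthropod", "worm_like", "worm_like",
           "polyphagous", "omnivore")
  m <- fit_feeding_model(vr, lab)
  expect_equal(m$fit_report$n_obs, 8)          # 4 single + 2 duplicated
  # fractional weighting gives the same point estimates here (same
  # likelihood up to a factor on the duplicated rows' weight)
  mf <- fit_feeding_model(vr, lab, inclusion_policy = "fractional")
  expect_equal(m$provenance, "refit")
  expect_true(is.finite(mf$slope))
  expect_error(fit_feeding_model(c(0.2, 0.3), c(1, 1)), "single class")
  expect_error(fit_feeding_model(c(0.2, 0.3), c(1, 0)), "at least 2")
})

test_that("ROC and Gini behave as the rank statistic dictates", {
  r <- roc_curve(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0))
  expect_equal(r$auc, 1)
  expect_equal(r$gini, 1)
  expect_equal(r$curve$tpr[nrow(r$curve)], 1)

  set.seed(5)
  for (i in 1:5) {
    sc <- round(runif(60), 1)                  # heavy ties
    lb <- rbinom(60, 1, 0.5)
    if (length(unique(lb)) < 2) next
    r <- roc_curve(sc, lb)
    expect_equal(r$auc, pairwise_auc_oracle(sc, lb), tolerance = 1e-12)
    expect_equal(r$gini, 2 * r$auc - 1)
  }

  set.seed(9)
  sc <- runif(1000); lb <- rbinom(1000, 1, 0.5)
  expect_equal(roc_curve(sc, lb)$auc, 0.5, tolerance = 0.05)
  expect_error(roc_curve(sc, rep(1, 1000)), "both classes")
})

test_that("ROC agrees with the reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(13)
  sc <- c(runif(40, 0.2, 0.9), runif(40, 0.1, 0.7))
  lb <- rep(c(1, 0), each = 40)
  r <- roc_curve(sc, lb)
  ref <- as.numeric(pROC::auc(pROC::roc(lb, sc, quiet = TRUE,
                                        direction = "<")))
  expect_equal(r$auc, ref, tolerance = 1e-12)
})

test_that("conditional proportions rise with velocity ratio", {
  cd <- conditional_density(runif(50), rep(1, 50), bins = 5)
  expect_true(all(cd$prop == 1))
  expect_true(all(cd$upper <= 1 & cd$lower >= 0))

  set.seed(17)
  vr <- runif(4000, 0.05, 0.9)
  y <- rbinom(4000, 1, plogis(1.4 + 2.6 * transform_vr(vr)))
  cd <- conditional_density(vr, y, bins = 5)
  expect_equal(nrow(cd), 5)
  expect_true(all(diff(cd$prop) > -0.05))      # monotone within noise

  # the training species show the same rising pattern
  tl <- training_labels()
  tr <- tl[tl$label %in% c("worm_like", "microarthropod", "polyphagous",
                           "omnivore") & tl$role == "training", ]
  lab <- ifelse(tr$label == "worm_like", 1,
                ifelse(tr$label == "microarthropod", 0, NA))
  ok <- !is.na(lab)
  cd2 <- conditional_density(tr$VR[ok], lab[ok], bins = 3)
  expect_gt(cd2$prop[3], cd2$prop[1])
  expect_error(conditional_density(1:3, c(0, 1, 0), bins = 5), "at least")
})
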