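test_that("IRLS logistic matches the closed-form 2x2 contingency solution", {
  # exposed: 30 cases / 20 controls; unexposed: 10 cases / 40 controls
  x <- c(rep(1, 50), rep(0, 50))
  y <- c(rep(1, 30), rep(0, 20), rep(1, 10), rep(0, 40))
  fit <- fit_logistic_irls(cbind(intercept = 1, exposure = x), y)
  expect_equal(exp(fit$coefficients[["exposure"]]),
               (30 * 40) / (20 * 10), tolerance = 1e-8)
  expect_equal(sqrt(fit$vcov["exposure", "exposure"]),
               sqrt(1 / 30 + 1 / 20 + 1 / 10 + 1 / 40), tolerance = 1e-8)
})

test_that("IRLS is unbiased under the null and exact on balanced data", {
  withr_seed(40, {
    x <- rnorm(1e4)
    y <- rbinom(1e4, 1, 0.4)
  })
  fit <- fit_logistic_irls(cbind(1, x = x), y)
  expect_lt(abs(fit$coefficients[["x"]]), 3 * sqrt(fit$vcov["x", "x"]))

  y50 <- rep(c(0, 1), 50)
  fit0 <- fit_logistic_irls(matrix(1, 100), y50)
  expect_equal(fit0$coefficients[[1]], 0, tolerance = 1e-10)
})

test_that("IRLS raises explicit errors for separation and rank deficiency", {
  withr_seed(41, {
    x <- rnorm(100)
  })
  expect_error(
    fit_logistic_irls(cbind(1, x = x), as.numeric(x > 0)),
    "separation"
  )
  expect_error(
    fit_logistic_irls(cbind(1, x = x, x2 = 2 * x), rbinom(100, 1, 0.5)),
    "rank-deficient"
  )
})

test_that("GEE with independence working correlation reproduces IRLS", {
  withr_seed(42, {
    d <- simulate_paired_logistic(80, beta = 0.5, random_effect_sd = 0.7)
  })
  x <- cbind(intercept = 1, score = d$x)
  irls <- fit_logistic_irls(x, d$y)
  gee <- fit_gee_logistic(x, d$y, d$cluster, working = "independence")
  expect_equal(gee$coefficients, irls$coefficients, tolerance = 1e-8)
  # sandwich SEs legitimately differ from the model-based ones
  expect_false(isTRUE(all.equal(diag(gee$robust_vcov), diag(irls$vcov))))
})

test_that("GEE on singleton clusters reduces to IRLS with HC0 sandwich", {
  withr_seed(43, {
    n <- 150
    x <- cbind(intercept = 1, score = rnorm(n), age = rnorm(n, 26, 4))
    y <- rbinom(n, 1, plogis(0.3 * x[, "score"]))
  })
  irls <- fit_logistic_irls(x, y)
  gee <- fit_gee_logistic(x, y, cluster_ids = seq_len(n),
                          working = "exchangeable")
  expect_equal(gee$coefficients, irls$coefficients, tolerance = 1e-8)
  # independent oracle for the sandwich: HC0 heteroskedasticity-robust
  # covariance of the equivalent glm fit
  glmfit <- glm(y ~ x[, "score"] + x[, "age"], family = binomial())
  hc0 <- sandwich::vcovHC(glmfit, type = "HC0")
  expect_equal(unname(gee$robust_vcov), unname(hc0), tolerance = 1e-6)
})

test_that("exchangeable alpha picks up the induced hip pairing", {
  withr_seed(44, {
    d <- simulate_paired_logistic(400, beta = 0, random_effect_sd = 1.5)
  })
  gee <- fit_gee_logistic(cbind(1, x = d$x), d$y, d$cluster)
  expect_gt(gee$alpha, 0.05)
  expect_true(gee$converged)
})

test_that("clustering inflates the sandwich SE of a cluster-constant term", {
  withr_seed(45, {
    wins <- replicate(200, {
      n_cl <- 40
      cl <- rep(seq_len(n_cl), each = 2)
      x_cl <- rnorm(n_cl)[cl]           # constant within cluster
      u <- rnorm(n_cl, 0, 1)[cl]
      y <- as.numeric(runif(2 * n_cl) < plogis(0.4 * x_cl + u))
      x <- cbind(1, x = x_cl)
      fit <- tryCatch(
        fit_gee_logistic(x, y, cl, working = "independence"),
        error = function(e) NULL
      )
      if (is.null(fit)) return(NA)
      sqrt(fit$robust_vcov["x", "x"]) > sqrt(fit$model_vcov["x", "x"])
    })
  })
  expect_gt(mean(wins, na.rm = TRUE), 0.5)
})

test_that("per-SD odds ratios and Wald intervals follow the plug-in rules", {
  fake <- list(
    coefficients = c(intercept = 0.1, score = log(1.34)),
    robust_vcov = diag(c(0.01, 0.118^2))
  )
  dimnames(fake$robust_vcov) <- list(names(fake$coefficients),
                                     names(fake$coefficients))
  res <- or_per_sd(fake, "score")
  expect_equal(round(res$or, 2), 1.34)
  expect_equal(round(res$ci_low, 2), 1.06)
  expect_equal(round(res$ci_high, 2), 1.69)
  # log-symmetry of the Wald interval
  expect_equal(res$ci_low * res$ci_high, exp(2 * res$beta), tolerance = 1e-12)

  null_fit <- list(coefficients = c(score = 0),
                   robust_vcov = matrix(0.04, dimnames = list("score", "score")))
  res0 <- or_per_sd(null_fit, "score")
  expect_equal(res0$or, 1)
  expect_equal(res0$p, 1)
  expect_equal(res0$ci_low * res0$ci_high, 1, tolerance = 1e-12)
})

test_that("per-SD odds ratios compound multiplicatively over SDs", {
  expect_equal(or_at_k_sd(0.75, -3), 2.37)
  expect_equal(or_at_k_sd(0.61, -3), 4.41)
  expect_equal(or_at_k_sd(0.75, -1), 1.33)
  expect_equal(or_at_k_sd(1.7, 0), 1.00)
  expect_equal(or_at_k_sd(0.8, -2), or_at_k_sd(1 / 0.8, 2))
  expect_error(or_at_k_sd(-1, 2), "or_per_sd_value")
})

test_that("Bonferroni alpha divides 0.05 by the number of tested modes", {
  expect_equal(bonferroni_alpha(15), 0.0033)
  expect_equal(bonferroni_alpha(1), 0.05)
  expect_equal(bonferroni_alpha(20), 0.0025)
  expect_error(bonferroni_alpha(0))
})

test_that("association scan shape, failure propagation and rescaling", {
  withr_seed(46, {
    n_part <- 120
    cl <- rep(seq_len(n_part), each = 2)
    raw <- matrix(rnorm(2 * n_part * 4), ncol = 4) %*% diag(c(3, 2, 1, 0.5))
    u <- rnorm(n_part, 0, 0.5)[cl]
    std <- scale(raw)
    y <- as.numeric(runif(2 * n_part) < plogis(0.6 * std[, 2] + u))
    covs <- data.frame(
      age = rnorm(2 * n_part, 26, 4),
      bmi = rnorm(2 * n_part, 24.5, 2.5),
      symptomatic_status = sample(c("symptomatic", "other", "asymptomatic"),
                                  2 * n_part, replace = TRUE)
    )
  })
  scan <- run_association_scan(std, list(outcome = y), covs, cl,
                               selected_modes = 1:4)
  expect_equal(nrow(scan), 4)
  expect_equal(attr(scan, "bonferroni_alpha"), 0.0125)
  expect_true(all(!scan$failed))
  expect_true(all(scan$ci_low <= scan$or & scan$or <= scan$ci_high))
  expect_true(all(scan$or > 0))

  # invariance to affine rescaling of the raw scores (standardization
  # absorbs any positive affine map)
  std2 <- scale(sweep(raw, 2, c(10, 0.2, 5, 1), "*") + 3)
  scan2 <- run_association_scan(std2, list(outcome = y), covs, cl,
                                selected_modes = 1:4)
  expect_equal(scan$or, scan2$or)
  expect_equal(scan$aor, scan2$aor)
  expect_equal(scan$p, scan2$p)

  # a constant outcome separates every model: rows flagged, scan survives
  scan_fail <- run_association_scan(std, list(outcome = rep(1, 2 * n_part)),
                                    covs, cl, selected_modes = 1:4)
  expect_true(all(scan_fail$failed))
  expect_true(all(is.na(scan_fail$or)))
})

test_that("the scan detects a true mode effect and holds its size", {
  detected <- 0
  null_p <- c()
  for (s in 1:6) {
    withr_seed(500 + s, {
      n_part <- 150
      cl <- rep(seq_len(n_part), each = 2)
      std <- scale(matrix(rnorm(2 * n_part * 5), ncol = 5))
      u <- rnorm(n_part, 0, 0.5)[cl]
      y <- as.numeric(runif(2 * n_part) < plogis(log(1.8) * std[, 2] + u))
      covs <- data.frame(
        age = rnorm(2 * n_part, 26, 4),
        bmi = rnorm(2 * n_part, 24.5, 2.5),
        symptomatic_status = sample(c("symptomatic", "other", "asymptomatic"),
                                    2 * n_part, replace = TRUE)
      )
    })
    scan <- run_association_scan(std, list(outcome = y), covs, cl)
    row2 <- scan[scan$mode == 2, ]
    detected <- detected + (row2$aci_low > 1)
    null_p <- c(null_p, scan$ap[scan$mode != 2])
  }
  expect_gte(detected, 5)
  # null modes reject at roughly the nominal rate
  expect_lt(mean(null_p < 0.05), 0.25)
})

test_that("minimal detectable OR behaves analytically in its limits", {
  res <- minimal_detectable_or(
    n_hips = 300, prevalence = 0.35, power = 0.8, n_reps = 150, seed = 9,
    tol = 0.02
  )
  expect_gt(res$or, 1)
  expect_equal(res$or * res$or_reciprocal, 1, tolerance = 1e-12)
  expect_gte(res$power_at_or, 0.8)

  # doubling the sample size shrinks the detectable OR
  res2 <- minimal_detectable_or(
    n_hips = 600, prevalence = 0.35, power = 0.8, n_reps = 150, seed = 9,
    tol = 0.02
  )
  expect_lt(res2$or, res$or)

  expect_error(
    minimal_detectable_or(n_hips = 10, prevalence = 0.5, power = 0.99,
                          n_reps = 50, seed = 1, or_max = 1.05),
    "bracket"
  )
})
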