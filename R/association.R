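#' Maximum-likelihood logistic regression (IRLS)
#'
#' Binomial logit fit by iteratively reweighted least squares (via
#' `stats::glm.fit` with a 1e-12 convergence tolerance), with explicit
#' errors for rank-deficient designs and separated data. Serves as the
#' reference fit that the generalized-estimating-equation machinery must
#' reproduce under an independence working correlation.
#'
#' @param design Numeric design matrix (including the intercept column).
#' @param outcomes Binary outcome vector (0/1 or logical).
#' @return A list with `coefficients`, `vcov` (model-based, inverse Fisher
#'   information), `fitted`, `converged` and `iterations`.
#' @export
fit_logistic_irls <- function(design, outcomes) {
  design <- as.matrix(design)
  y <- as.numeric(outcomes)
  stopifnot(length(y) == nrow(design), all(y %in% c(0, 1)))
  if (qr(design)$rank < ncol(design)) {
    stop("rank-deficient design matrix: drop collinear columns")
  }
  fit <- suppressWarnings(stats::glm.fit(
    x = design, y = y, family = stats::binomial(),
    control = stats::glm.control(epsilon = 1e-12, maxit = 100)
  ))
  beta <- fit$coefficients
  mu <- fit$fitted.values
  if (!fit$converged || max(abs(beta)) > 30 ||
      any(mu < 1e-10 & y == 1) || any(mu > 1 - 1e-10 & y == 0) ||
      (any(mu < 1e-10 | mu > 1 - 1e-10) && max(abs(beta)) > 15)) {
    stop("separation (or non-convergence): logistic coefficients diverge; ",
         "the outcome is perfectly predicted in part of the design space")
  }
  w <- mu * (1 - mu)
  info <- crossprod(design * sqrt(w))
  list(
    coefficients = stats::setNames(beta, colnames(design)),
    vcov = solve(info),
    fitted = mu,
    converged = fit$converged,
    iterations = fit$iter
  )
}

#' GEE logistic regression with sandwich variance
#'
#' Liang-Zeger generalized estimating equations for a marginal logistic
#' model with clustered binary outcomes (here: the two hips of one
#' participant). Fisher scoring on the estimating equations with working
#' covariance `V_i = phi * A_i^(1/2) R(alpha) A_i^(1/2)`; the exchangeable
#' correlation `alpha` is re-estimated each iteration by the moment
#' estimator from within-cluster cross-products of standardized Pearson
#' residuals. The coefficient covariance is the robust sandwich
#' `B^-1 M B^-1` with bread `B = sum D_i' V_i^-1 D_i` and meat
#' `M = sum D_i' V_i^-1 r_i r_i' V_i^-1 D_i`; the model-based covariance
#' `B^-1` is also returned. Initialised at the independence IRLS fit.
#'
#' @param design Numeric design matrix (including intercept).
#' @param outcomes Binary outcome vector.
#' @param cluster_ids Cluster identifier per observation.
#' @param working Working correlation: `"exchangeable"` (default) or
#'   `"independence"`.
#' @param max_iter,tol Fisher-scoring iteration cap and coefficient-change
#'   tolerance.
#' @param small_sample `"none"` (default) or `"mancl-derouen"` for the
#'   Mancl-DeRouen small-sample correction of the sandwich meat.
#' @return An object of class `gee_fit`: `coefficients`, `robust_vcov`,
#'   `model_vcov`, `alpha` (working correlation estimate), `phi`
#'   (dispersion), `n_clusters`, `n_obs`, `iterations`, `converged`.
#' @export
fit_gee_logistic <- function(design, outcomes, cluster_ids,
                             working = c("exchangeable", "independence"),
                             max_iter = 50, tol = 1e-10,
                             small_sample = c("none", "mancl-derouen")) {
  working <- match.arg(working)
  small_sample <- match.arg(small_sample)
  design <- as.matrix(design)
  y <- as.numeric(outcomes)
  stopifnot(length(y) == nrow(design), length(cluster_ids) == nrow(design))

  ord <- order(as.character(cluster_ids))
  x <- design[ord, , drop = FALSE]
  y <- y[ord]
  cl <- as.character(cluster_ids)[ord]
  idx <- split(seq_along(cl), factor(cl, levels = unique(cl)))
  n_clusters <- length(idx)
  n_obs <- length(y)
  p <- ncol(x)

  init <- fit_logistic_irls(x, y)
  beta <- init$coefficients

  alpha <- 0
  phi <- 1
  converged <- FALSE
  iterations <- 0L
  for (it in seq_len(max_iter)) {
    iterations <- it
    eta <- drop(x %*% beta)
    mu <- stats::plogis(eta)
    v <- mu * (1 - mu)
    e <- (y - mu) / sqrt(v)

    phi <- sum(e^2) / (n_obs - p)
    if (working == "exchangeable") {
      cross <- 0
      n_pairs <- 0
      for (ii in idx) {
        ni <- length(ii)
        if (ni > 1) {
          ei <- e[ii]
          cross <- cross + (sum(ei)^2 - sum(ei^2)) / 2
          n_pairs <- n_pairs + ni * (ni - 1) / 2
        }
      }
      alpha <- if (n_pairs > p) cross / ((n_pairs - p) * phi) else 0
      if (abs(alpha) > 0.99) {
        warning("working correlation estimate ", round(alpha, 3),
                " clipped to (-0.99, 0.99)")
        alpha <- sign(alpha) * 0.99
      }
    }

    bread <- matrix(0, p, p)
    u <- numeric(p)
    for (ii in idx) {
      ni <- length(ii)
      xi <- x[ii, , drop = FALSE]
      vi <- v[ii]
      ri <- y[ii] - mu[ii]
      di <- xi * vi
      r_mat <- matrix(alpha, ni, ni)
      diag(r_mat) <- 1
      v_i <- phi * (sqrt(vi) %o% sqrt(vi)) * r_mat
      v_inv <- solve(v_i)
      bread <- bread + crossprod(di, v_inv %*% di)
      u <- u + drop(crossprod(di, v_inv %*% ri))
    }
    step <- solve(bread, u)
    beta <- beta + step
    if (max(abs(step)) < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("GEE did not converge in ", max_iter, " iterations")
  }

  ## sandwich at the final beta
  eta <- drop(x %*% beta)
  mu <- stats::plogis(eta)
  v <- mu * (1 - mu)
  bread <- matrix(0, p, p)
  cluster_parts <- vector("list", n_clusters)
  for (j in seq_along(idx)) {
    ii <- idx[[j]]
    ni <- length(ii)
    xi <- x[ii, , drop = FALSE]
    vi <- v[ii]
    di <- xi * vi
    r_mat <- matrix(alpha, ni, ni)
    diag(r_mat) <- 1
    v_i <- phi * (sqrt(vi) %o% sqrt(vi)) * r_mat
    v_inv <- solve(v_i)
    bread <- bread + crossprod(di, v_inv %*% di)
    cluster_parts[[j]] <- list(ii = ii, di = di, v_inv = v_inv)
  }
  b_inv <- solve(bread)
  meat <- matrix(0, p, p)
  for (cp in cluster_parts) {
    ri <- y[cp$ii] - mu[cp$ii]
    if (small_sample == "mancl-derouen") {
      h_i <- cp$di %*% b_inv %*% t(cp$di) %*% cp$v_inv
      ri <- drop(solve(diag(length(ri)) - h_i, ri))
    }
    g <- drop(crossprod(cp$di, cp$v_inv %*% ri))
    meat <- meat + tcrossprod(g)
  }
  robust <- b_inv %*% meat %*% b_inv
  dimnames(robust) <- dimnames(b_inv) <- list(colnames(x), colnames(x))

  structure(
    list(
      coefficients = stats::setNames(beta, colnames(x)),
      robust_vcov = robust,
      model_vcov = b_inv,
      alpha = if (working == "exchangeable") alpha else 0,
      phi = phi,
      working = working,
      n_clusters = n_clusters,
      n_obs = n_obs,
      iterations = iterations,
      converged = converged
    ),
    class = "gee_fit"
  )
}

#' @export
print.gee_fit <- function(x, ...) {
  cat("<gee_fit> ", x$n_obs, " obs in ", x$n_clusters, " clusters, ",
      x$working, " working correlation",
      if (x$working == "exchangeable") sprintf(" (alpha = %.3f)", x$alpha),
      "\n", sep = "")
  se <- sqrt(diag(x$robust_vcov))
  print(cbind(estimate = x$coefficients, robust_se = se))
  invisible(x)
}

#' Odds ratio per SD with robust Wald confidence interval
#'
#' For a fit whose exposure is on the standardized (per-SD) scale:
#' `OR = exp(beta)`, 95% CI `exp(beta +/- 1.96 * robust SE)`, two-sided
#' normal Wald p-value.
#'
#' @param fit A [fit_gee_logistic()] (or [fit_logistic_irls()]) result.
#' @param exposure_term Name or index of the exposure coefficient.
#' @param conf_z Normal quantile for the CI (default 1.96).
#' @return A list with `or`, `ci_low`, `ci_high`, `p`, `beta`, `se`
#'   (unrounded; round to 2 decimals for reporting).
#' @export
or_per_sd <- function(fit, exposure_term, conf_z = 1.96) {
  beta <- fit$coefficients[[exposure_term]]
  vc <- if (!is.null(fit$robust_vcov)) fit$robust_vcov else fit$vcov
  se <- sqrt(vc[exposure_term, exposure_term])
  z <- beta / se
  list(
    or = exp(beta),
    ci_low = exp(beta - conf_z * se),
    ci_high = exp(beta + conf_z * se),
    p = 2 * stats::pnorm(-abs(z)),
    beta = beta,
    se = se
  )
}

#' Convert a per-SD odds ratio to the odds ratio at k SD
#'
#' A per-SD odds ratio compounds multiplicatively over SDs:
#' `OR^k`, reported to two decimals. For a protective per-SD OR and
#' negative `k` this equals `(1/OR)^|k|` — e.g. a per-SD OR of 0.75 gives
#' an OR of 2.37 at -3 SD.
#'
#' @param or_per_sd_value Per-SD odds ratio (> 0).
#' @param k Signed number of SDs.
#' @return The odds ratio at `k` SD, rounded to two decimals.
#' @export
or_at_k_sd <- function(or_per_sd_value, k) {
  stopifnot(or_per_sd_value > 0)
  round(or_per_sd_value^k, 2)
}

#' Bonferroni-adjusted significance level
#'
#' `0.05 / n_modes`, reported to four decimals (e.g. 0.0033 for 15 tested
#' shape modes).
#'
#' @param n_modes Number of tested shape modes (>= 1).
#' @return The adjusted alpha, rounded to four decimals.
#' @export
bonferroni_alpha <- function(n_modes) {
  stopifnot(n_modes >= 1)
  round(0.05 / n_modes, 4)
}

#' Per-mode association scan of shape scores with binary outcomes
#'
#' Fits, for every selected shape mode and every outcome, a crude GEE
#' logistic model (mode score only) and an adjusted model (mode score +
#' age + BMI + symptomatic-status dummies with asymptomatic as reference,
#' keeping "other" hips distinct), clustering on participant. Reports
#' odds ratios per SD with robust 95% Wald CIs and p-values, flags at the
#' 0.05 and Bonferroni levels (on the adjusted p-value), and propagates
#' per-row fit failures (e.g. separation) without aborting the scan.
#' Rows with missing covariates are dropped per model (complete case),
#' with a message giving the count.
#'
#' @param scores Matrix of standardized mode scores (one column per mode,
#'   one row per hip).
#' @param outcomes Data.frame/list of logical outcome vectors (one element
#'   per outcome, e.g. `cartilage_defect`, `labral_tear`).
#' @param covariates Data.frame with columns `age`, `bmi`,
#'   `symptomatic_status`.
#' @param cluster_ids Participant identifier per hip.
#' @param selected_modes Integer indices of the modes to test (default all
#'   columns of `scores`).
#' @param working Working correlation, passed to [fit_gee_logistic()].
#' @return A data.frame with one row per (mode, outcome):
#'   `mode`, `outcome`, `or`, `ci_low`, `ci_high`, `p`, `aor`, `aci_low`,
#'   `aci_high`, `ap`, `sig_05`, `sig_bonferroni`, `failed`; odds ratios
#'   and CIs rounded to 2 decimals, p-values to 4. The Bonferroni alpha is
#'   attached as attribute `"bonferroni_alpha"`.
#' @export
run_association_scan <- function(scores, outcomes, covariates, cluster_ids,
                                 selected_modes = seq_len(ncol(scores)),
                                 working = "exchangeable") {
  scores <- as.matrix(scores)
  alpha_bonf <- bonferroni_alpha(length(selected_modes))
  status <- covariates$symptomatic_status
  covs <- cbind(
    age = covariates$age,
    bmi = covariates$bmi,
    symptomatic = as.numeric(status == "symptomatic"),
    other = as.numeric(status == "other")
  )

  rows <- list()
  for (out_name in names(outcomes)) {
    y_all <- as.numeric(outcomes[[out_name]])
    for (m in selected_modes) {
      z <- scores[, m]
      keep <- stats::complete.cases(z, y_all, covs)
      if (sum(!keep) > 0) {
        message("mode ", m, " / ", out_name, ": dropped ", sum(!keep),
                " incomplete row(s)")
      }
      row <- data.frame(
        mode = m, outcome = out_name,
        or = NA_real_, ci_low = NA_real_, ci_high = NA_real_, p = NA_real_,
        aor = NA_real_, aci_low = NA_real_, aci_high = NA_real_,
        ap = NA_real_,
        sig_05 = NA, sig_bonferroni = NA, failed = FALSE,
        stringsAsFactors = FALSE
      )
      res <- tryCatch({
        x_crude <- cbind(intercept = 1, score = z[keep])
        x_adj <- cbind(x_crude, covs[keep, , drop = FALSE])
        fit_c <- fit_gee_logistic(x_crude, y_all[keep], cluster_ids[keep],
                                  working = working)
        fit_a <- fit_gee_logistic(x_adj, y_all[keep], cluster_ids[keep],
                                  working = working)
        crude <- or_per_sd(fit_c, "score")
        adj <- or_per_sd(fit_a, "score")
        list(crude = crude, adj = adj)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        row$failed <- TRUE
      } else {
        row$or <- round(res$crude$or, 2)
        row$ci_low <- round(res$crude$ci_low, 2)
        row$ci_high <- round(res$crude$ci_high, 2)
        row$p <- round(res$crude$p, 4)
        row$aor <- round(res$adj$or, 2)
        row$aci_low <- round(res$adj$ci_low, 2)
        row$aci_high <- round(res$adj$ci_high, 2)
        row$ap <- round(res$adj$p, 4)
        row$sig_05 <- res$adj$p < 0.05
        row$sig_bonferroni <- res$adj$p < alpha_bonf
      }
      rows[[length(rows) + 1]] <- row
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$outcome, out$mode), ]
  rownames(out) <- NULL
  attr(out, "bonferroni_alpha") <- alpha_bonf
  out
}

#' Minimal detectable per-SD odds ratio by simulation
#'
#' The smallest per-SD odds ratio whose empirical Wald power at level
#' `alpha` reaches the target, for a continuous standard-normal predictor
#' with the given sample size, outcome prevalence and paired-hip
#' clustering. Found by bisection on the log odds ratio with common random
#' numbers across candidate values (so power is monotone over the
#' bisection), each candidate evaluated over `n_reps` simulated cohorts
#' fitted with the exchangeable GEE.
#'
#' @param n_hips Number of hips (observations).
#' @param prevalence Baseline outcome prevalence (0-1).
#' @param power Target power (default 0.8).
#' @param alpha Test level (default 0.05).
#' @param cluster_size Hips per participant (default 2).
#' @param random_effect_sd Participant-level logit random-effect SD
#'   inducing within-cluster correlation (default 0.5).
#' @param n_reps Replicates per candidate (default 2000).
#' @param seed Seed for the common random numbers.
#' @param tol Bisection tolerance on the log odds ratio.
#' @param or_max Upper bracket for the odds ratio (default 6).
#' @return A list with `or` (>= 1), `or_reciprocal` (= 1/or, the
#'   detectable protective OR), and `power_at_or`.
#' @export
minimal_detectable_or <- function(n_hips, prevalence, power = 0.8,
                                  alpha = 0.05, cluster_size = 2,
                                  random_effect_sd = 0.5, n_reps = 2000,
                                  seed = 1, tol = 0.01, or_max = 6) {
  stopifnot(prevalence > 0, prevalence < 1, power > 0, power < 1)
  n_clusters <- ceiling(n_hips / cluster_size)
  draws <- with_seed(seed, {
    lapply(seq_len(n_reps), function(r) {
      cl <- rep(seq_len(n_clusters), each = cluster_size)[seq_len(n_hips)]
      list(
        x = stats::rnorm(n_hips),
        u = stats::rnorm(n_clusters, 0, random_effect_sd)[cl],
        uu = stats::runif(n_hips),
        cl = cl
      )
    })
  })
  beta0 <- stats::qlogis(prevalence)
  power_at <- function(log_or) {
    hits <- vapply(draws, function(d) {
      y <- as.numeric(d$uu < stats::plogis(beta0 + log_or * d$x + d$u))
      p <- tryCatch(suppressWarnings({
        fit <- fit_gee_logistic(cbind(1, x = d$x), y, d$cl,
                                working = "exchangeable")
        or_per_sd(fit, "x")$p
      }), error = function(e) NA_real_)
      isTRUE(p < alpha)
    }, logical(1))
    mean(hits)
  }
  lo <- 0
  hi <- log(or_max)
  if (power_at(hi) < power) {
    stop("bisection bracket failure: power at OR = ", or_max,
         " is below the target; increase or_max or n_hips")
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (power_at(mid) >= power) hi <- mid else lo <- mid
  }
  or <- exp(hi)
  list(or = or, or_reciprocal = 1 / or, power_at_or = power_at(hi))
}
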