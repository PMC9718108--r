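# shared fixture builders; everything is generated in code at test time

# shapes drawn from a known low-rank deformation model, no nuisance
# transforms: template + sum_j sqrt(lambda_j) z_j v_j (+ optional noise)
make_truth_shapes <- function(n, eigenvalues, noise_sd = 0, seed = 42,
                              sex = "male") {
  tpl <- make_template(sex)
  basis <- make_mode_basis(tpl, length(eigenvalues), seed = seed + 1)
  withr_seed(seed, {
    z <- matrix(rnorm(n * length(eigenvalues)), n)
    # whiten the scores (exact zero mean, identity sample covariance) so
    # the prescribed eigenvalues are realised exactly in-sample
    z <- scale(z, scale = FALSE)
    z <- z %*% solve(chol(stats::cov(z)))
    flat <- matrix(rep(flatten_points(tpl$points), n), n, byrow = TRUE) +
      z %*% (t(basis) * sqrt(eigenvalues)) +
      matrix(rnorm(n * 164, 0, noise_sd), n)
    list(shapes = flat, z = z, basis = basis, eigenvalues = eigenvalues,
         template = tpl)
  })
}

# local seed without touching the session RNG stream permanently
withr_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  code
}

# a minimal valid hip-table row
hip_row <- function(participant_id = "P001", side = "right", sex = "male",
                    age = 26, bmi = 24.5, symptomatic_status = "asymptomatic",
                    kl_grade = 0, cartilage = rep(0L, 10), labral = rep(0L, 4)) {
  row <- data.frame(
    participant_id = participant_id, side = side, sex = sex, age = age,
    bmi = bmi, symptomatic_status = symptomatic_status, kl_grade = kl_grade,
    stringsAsFactors = FALSE
  )
  row[paste0("cartilage_", 1:10)] <- as.list(cartilage)
  row[paste0("labral_", 1:4)] <- as.list(labral)
  row
}

# a shape_model-shaped object with prescribed variance fractions, for
# exercising the mode-selection rule against printed variance profiles
fake_model_with_fractions <- function(fractions) {
  structure(
    list(variance_fraction = fractions,
         eigenvalues = fractions,
         modes = matrix(0, 2, length(fractions))),
    class = "shape_model"
  )
}

# brute-force rotation oracle: two-stage grid search over the rotation
# angle minimising summed squared distance to the reference
grid_rotation_angle <- function(shape, reference, fine_step = 0.002) {
  obj <- function(theta_deg) {
    th <- theta_deg * pi / 180
    r <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    sum((shape %*% t(r) - reference)^2)
  }
  coarse <- seq(-180, 180, by = 0.5)
  v <- vapply(coarse, obj, numeric(1))
  best <- coarse[which.min(v)]
  fine <- seq(best - 1, best + 1, by = fine_step)
  v <- vapply(fine, obj, numeric(1))
  fine[which.min(v)]
}

# angle of the row-vector action x %*% r (counter-clockwise, degrees)
rotation_angle_deg <- function(r) atan2(r[1, 2], r[1, 1]) * 180 / pi

# paired-hip logistic cohorts for calibration checks: standard-normal
# exposure, participant random intercept shared by the two hips
simulate_paired_logistic <- function(n_participants, beta, beta0 = 0,
                                     random_effect_sd = 0.5) {
  n <- 2 * n_participants
  cl <- rep(seq_len(n_participants), each = 2)
  x <- rnorm(n)
  u <- rnorm(n_participants, 0, random_effect_sd)[cl]
  y <- as.numeric(runif(n) < plogis(beta0 + beta * x + u))
  list(x = x, y = y, cluster = cl)
}
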