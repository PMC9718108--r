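test_that("template has 82 labelled points, centred, with smooth segments", {
  for (sex in c("male", "female")) {
    tpl <- make_template(sex)
    expect_equal(nrow(tpl$points), 82)
    expect_equal(
      as.vector(table(tpl$segment_labels)[c(
        "head_arc", "headneck_junction", "lateral_neck", "medial_neck",
        "acetabular_rim"
      )]),
      c(30, 7, 15, 8, 22)
    )
    expect_lt(max(abs(colMeans(tpl$points))), 1e-9)
    # consecutive points within a segment stay close (polyline smoothness)
    d <- sqrt(rowSums(diff(tpl$points)^2))
    same_seg <- tpl$segment_labels[-82] == tpl$segment_labels[-1]
    expect_lt(max(d[same_seg]), 6)
  }
})

test_that("male and female templates differ only in scale-bearing parts", {
  m <- make_template("male")
  f <- make_template("female")
  expect_equal(nrow(m$points), nrow(f$points))
  expect_equal(m$head_radius, 25)
  expect_equal(f$head_radius, 22)
  expect_false(isTRUE(all.equal(m$points, f$points)))
})

test_that("head-arc sampling spaces points by r * dtheta", {
  tpl <- make_template("male")
  head <- tpl$points[tpl$segment_labels == "head_arc", ]
  d <- sqrt(rowSums(diff(head)^2))
  # equal chords, equal to the arc length 25 * (220/29 deg) up to the
  # chord-vs-arc difference (< 0.01 mm at this angular step)
  expect_lt(diff(range(d)), 1e-9)
  expect_equal(d[1], 25 * (220 / 29) * pi / 180, tolerance = 1e-3)
})

test_that("mode basis is orthonormal and orthogonal to similarity space", {
  tpl <- make_template("male")
  b <- make_mode_basis(tpl, n_modes = 3, seed = 11)
  expect_equal(dim(b), c(164, 3))
  expect_lt(max(abs(crossprod(b) - diag(3))), 1e-10)
  sim <- similarity_basis(flatten_points(tpl$points))
  expect_lt(max(abs(crossprod(sim, b))), 1e-8)
})

test_that("a deformation mode survives similarity projection by construction", {
  # shifting the template along a mode cannot be undone by Procrustes:
  # the mode has no component in the analytically constructed similarity
  # subspace at the template
  tpl <- make_template("female")
  b <- make_mode_basis(tpl, n_modes = 5, seed = 2)
  sim <- similarity_basis(flatten_points(tpl$points))
  for (j in 1:5) {
    expect_lt(max(abs(crossprod(sim, b[, j]))), 1e-8)
  }
})

test_that("mode basis is deterministic given the seed and bounded in count", {
  tpl <- make_template("male")
  expect_identical(make_mode_basis(tpl, 4, seed = 7),
                   make_mode_basis(tpl, 4, seed = 7))
  expect_false(identical(make_mode_basis(tpl, 4, seed = 7),
                         make_mode_basis(tpl, 4, seed = 8)))
  expect_error(make_mode_basis(tpl, 161, seed = 1), "n_modes")
})

test_that("shomri grades encode the outcome flags and round-trip exactly", {
  neg <- simulate_shomri(FALSE, FALSE, seed = 1)
  expect_true(all(neg$cartilage == 0))
  expect_true(all(neg$labral %in% 0:1))

  for (a in c(FALSE, TRUE)) {
    for (b in c(FALSE, TRUE)) {
      for (s in 1:25) {
        g <- simulate_shomri(a, b, seed = s)
        expect_identical(cartilage_defect_present(g$cartilage), a)
        expect_identical(labral_tear_present(g$labral), b)
      }
    }
  }
})

test_that("1000 labral-only draws give 0 cartilage and 1000 labral positives", {
  withr_seed(99, {
    flags <- t(replicate(1000, {
      g <- simulate_shomri(FALSE, TRUE)
      c(cartilage_defect_present(g$cartilage), labral_tear_present(g$labral))
    }))
  })
  expect_equal(sum(flags[, 1]), 0)
  expect_equal(sum(flags[, 2]), 1000)
})

test_that("generator config validates its invariants", {
  expect_error(generator_config(n_true_modes = 200), "n_true_modes")
  expect_error(generator_config(eigen_decay = -1), "eigen_decay")
  expect_error(generator_config(random_effect_sd = -0.1), "random_effect_sd")
  expect_error(generator_config(kl_positive_prob = 1.5), "kl_positive_prob")
  expect_error(
    generator_config(n_true_modes = 3, eigenvalues = c(1, 2)),
    "eigenvalues"
  )
})

test_that("cohort generation is deterministic at the file level", {
  cfg <- generator_config(n_participants = 15, seed = 123)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$clinical, b$clinical)
  expect_identical(a$landmarks[[5]]$points, b$landmarks[[5]]$points)
  expect_identical(a$truth$scores, b$truth$scores)

  d1 <- file.path(tempdir(), "cohA")
  d2 <- file.path(tempdir(), "cohB")
  unlink(c(d1, d2), recursive = TRUE)
  write_cohort(a, d1, cfg)
  write_cohort(b, d2, cfg)
  f <- list.files(d1, recursive = TRUE)
  expect_identical(unname(tools::md5sum(file.path(d1, f))),
                   unname(tools::md5sum(file.path(d2, f))))
})

test_that("a null outcome model gives ~50% prevalence and no hip pairing", {
  cfg <- generator_config(
    n_participants = 250, seed = 7,
    effect_spec = list(cartilage = numeric(0), labral = numeric(0)),
    covariate_effects = c(age = 0, bmi = 0, symptomatic = 0, other = 0),
    baseline_logit = c(cartilage = 0, labral = 0),
    random_effect_sd = 0
  )
  co <- simulate_cohort(cfg)
  cl <- derive_outcomes(co$clinical)
  n <- nrow(cl)
  prev <- mean(cl$cartilage_defect_present)
  expect_lt(abs(prev - 0.5), 3 * sqrt(0.25 / n))

  # sigma_u = 0: outcomes of the two hips of one participant uncorrelated
  y1 <- cl$cartilage_defect_present[cl$side == "right"]
  y2 <- cl$cartilage_defect_present[cl$side == "left"]
  expect_lt(abs(cor(y1, y2)), 3 / sqrt(length(y1)))
})

test_that("true mode scores are standard normal over a large cohort", {
  cfg <- generator_config(n_participants = 500, seed = 31)
  co <- simulate_cohort(cfg)
  sds <- apply(co$truth$scores, 2, sd)
  expect_true(all(sds > 0.93 & sds < 1.07))
  expect_gte(nrow(co$truth$scores), 1000)
})

test_that("a single-mode effect is recovered by logistic regression on truth", {
  beta_true <- log(1.5)
  cfg <- generator_config(
    n_participants = 200, seed = 17,
    effect_spec = list(cartilage = c("1" = beta_true), labral = numeric(0)),
    covariate_effects = c(age = 0, bmi = 0, symptomatic = 0, other = 0),
    baseline_logit = c(cartilage = 0, labral = 0),
    random_effect_sd = 0
  )
  co <- simulate_cohort(cfg)
  cl <- derive_outcomes(co$clinical)
  z1 <- co$truth$scores[, 1]
  fit <- fit_logistic_irls(cbind(1, z = z1), cl$cartilage_defect_present)
  se <- sqrt(fit$vcov["z", "z"])
  expect_lt(abs(fit$coefficients[["z"]] - beta_true), 3 * se)
})

test_that("status assignment matches the requested hip-level marginals", {
  cfg <- generator_config(n_participants = 2000, seed = 5)
  co <- simulate_cohort(cfg)
  p <- prop.table(table(co$clinical$symptomatic_status))
  expect_equal(unname(p[["symptomatic"]]), 0.629, tolerance = 0.05)
  expect_equal(unname(p[["other"]]), 0.157, tolerance = 0.15)
  expect_equal(unname(p[["asymptomatic"]]), 0.214, tolerance = 0.12)
  # "other" hips only occur in participants that also have a symptomatic hip
  by_part <- split(co$clinical$symptomatic_status, co$clinical$participant_id)
  for (st in by_part) {
    if ("other" %in% st) expect_true("symptomatic" %in% st)
  }
})
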