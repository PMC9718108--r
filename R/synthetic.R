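#' Orthonormal basis of the similarity subspace at a template
#'
#' The four directions in flattened coordinate space (length 2k, stacked
#' x then y) that a similarity transform can move a centred configuration
#' along: x-translation, y-translation, scaling (the template itself) and
#' infinitesimal rotation. For a centred template these four vectors are
#' exactly orthogonal; they are returned normalised, as a `2k x 4` matrix.
#'
#' @param template_flat Flattened, centred template coordinates (length 2k).
#' @return A `2k x 4` matrix with orthonormal columns
#'   (`tx`, `ty`, `scale`, `rotation`).
#' @export
similarity_basis <- function(template_flat) {
  n2 <- length(template_flat)
  k <- n2 / 2L
  xs <- template_flat[seq_len(k)]
  ys <- template_flat[k + seq_len(k)]
  stopifnot(abs(mean(xs)) < 1e-6, abs(mean(ys)) < 1e-6)
  tx <- c(rep(1, k), rep(0, k)) / sqrt(k)
  ty <- c(rep(0, k), rep(1, k)) / sqrt(k)
  sc <- template_flat / sqrt(sum(template_flat^2))
  ro <- c(-ys, xs) / sqrt(sum(xs^2 + ys^2))
  cbind(tx = tx, ty = ty, scale = sc, rotation = ro)
}

#' Smooth random deformation modes orthogonal to similarity transforms
#'
#' Draws standard-normal vectors in the flattened coordinate space, smooths
#' each coordinate channel along the point index with a centred moving
#' average (partial windows at the ends), projects out the four similarity
#' directions and all previously accepted modes (Gram-Schmidt), and
#' normalises. The result is a set of orthonormal deformation modes that
#' Procrustes alignment cannot remove — the ground-truth shape variation of
#' the synthetic cohort.
#'
#' @param template A `hip_template` from [make_template()].
#' @param n_modes Number of modes J (at most `2 * n_points - 4`).
#' @param smooth_window Width of the centred moving average (default 7).
#' @param seed Integer seed; the basis is deterministic given the seed.
#' @return A `2k x n_modes` matrix with orthonormal columns, each orthogonal
#'   to the similarity subspace at the template.
#' @export
make_mode_basis <- function(template, n_modes, smooth_window = 7, seed = 1) {
  k <- nrow(template$points)
  if (n_modes > 2 * k - 4) {
    stop("n_modes must be at most 2 * n_points - 4 = ", 2 * k - 4)
  }
  tflat <- flatten_points(template$points)
  sim <- similarity_basis(tflat)
  basis <- matrix(0, nrow = 2 * k, ncol = n_modes)
  with_seed(seed, {
    for (j in seq_len(n_modes)) {
      raw <- stats::rnorm(2 * k)
      v <- c(
        moving_average(raw[seq_len(k)], smooth_window),
        moving_average(raw[k + seq_len(k)], smooth_window)
      )
      prev <- cbind(sim, basis[, seq_len(j - 1), drop = FALSE])
      v <- v - prev %*% crossprod(prev, v)
      nv <- sqrt(sum(v^2))
      if (nv < 1e-8) {
        stop(
          "degenerate random draw: Gram-Schmidt residual norm ", nv,
          " < 1e-8 for mode ", j, "; retry with another seed"
        )
      }
      basis[, j] <- v / nv
    }
  })
  basis
}

## centred moving average with partial windows at the boundaries
moving_average <- function(x, width) {
  stopifnot(width >= 1)
  h <- (width - 1) %/% 2
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

## evaluate code under a temporary RNG state seeded with `seed`
with_seed <- function(seed, code) {
  if (is.null(seed)) return(eval.parent(substitute(code)))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  eval.parent(substitute(code))
}

#' Configuration for the synthetic cohort generator
#'
#' Collects and validates every knob of the synthetic study: cohort size and
#' sex split, the true deformation spectrum, landmark noise and nuisance
#' similarity transforms, the logistic outcome model (per-mode log odds
#' ratios, covariate effects, participant random effect), and clinical-table
#' rates. Defaults emulate the study conditions: 229 participants with the
#' observed sex split, 15 true modes with a decaying spectrum calibrated to
#' 2 mm RMS mode-1 displacement, outcome effects on modes 1, 12 and 15
#' (cartilage) and mode 12 (labral) at the reported adjusted per-SD odds
#' ratios, baseline prevalences 51.9% / 70.4%, and a 19/465 rate of
#' radiographic osteoarthritis (KL grade > 0).
#'
#' @param n_participants Number of participants (two hips each).
#' @param male_fraction Proportion of male participants.
#' @param n_true_modes Number J of true deformation modes.
#' @param eigen_decay Spectrum decay exponent gamma > 0 in
#'   `lambda_j = c * j^-gamma`.
#' @param eigenvalues Optional explicit eigenvalues (mm^2), overriding the
#'   power-law spectrum.
#' @param landmark_noise_sd Per-coordinate iid landmark noise SD (mm).
#' @param max_rotation_deg,scale_range,translation_mm Nuisance similarity
#'   transform ranges applied to every simulated hip.
#' @param effect_spec Named list with elements `cartilage` and `labral`,
#'   each a named numeric vector of log odds ratios per unit true mode
#'   score, names giving mode indices.
#' @param covariate_effects Named vector of log odds ratios: `age` (per
#'   year), `bmi` (per kg/m^2), `symptomatic` and `other` (status dummies
#'   versus asymptomatic).
#' @param random_effect_sd SD of the participant-level logit random effect.
#' @param baseline_logit Named vector (`cartilage`, `labral`) of intercepts
#'   on the logit scale at covariate reference values.
#' @param kl_positive_prob Probability a hip has KL grade > 0.
#' @param status_probs Hip-level marginal probabilities of the three
#'   symptomatic-status levels (`symptomatic`, `other`, `asymptomatic`).
#' @param seed Integer seed for the full generation.
#' @return A validated list of class `generator_config`.
#' @export
generator_config <- function(n_participants = 229,
                             male_fraction = 178 / 229,
                             n_true_modes = 15,
                             eigen_decay = 1.3,
                             eigenvalues = NULL,
                             landmark_noise_sd = 0.5,
                             max_rotation_deg = 10,
                             scale_range = c(0.9, 1.1),
                             translation_mm = 20,
                             effect_spec = list(
                               cartilage = c(
                                 "1" = log(0.75), "12" = log(1.34),
                                 "15" = log(0.61)
                               ),
                               labral = c("12" = log(1.30))
                             ),
                             covariate_effects = c(
                               age = log(1.02), bmi = log(1.05),
                               symptomatic = log(1.5), other = log(1.2)
                             ),
                             random_effect_sd = 0.5,
                             baseline_logit = c(
                               cartilage = stats::qlogis(0.519),
                               labral = stats::qlogis(0.704)
                             ),
                             kl_positive_prob = 19 / 465,
                             status_probs = c(
                               symptomatic = 0.629, other = 0.157,
                               asymptomatic = 0.214
                             ),
                             seed = 1) {
  stopifnot(
    n_participants >= 1,
    male_fraction >= 0, male_fraction <= 1,
    n_true_modes >= 1, n_true_modes <= 2 * 82 - 4,
    eigen_decay > 0,
    landmark_noise_sd >= 0,
    random_effect_sd >= 0,
    kl_positive_prob >= 0, kl_positive_prob <= 1,
    length(scale_range) == 2, scale_range[1] > 0,
    scale_range[1] <= scale_range[2]
  )
  if (!is.null(eigenvalues)) {
    stopifnot(length(eigenvalues) == n_true_modes, all(eigenvalues > 0))
  }
  for (spec in effect_spec) {
    if (length(spec) && any(as.integer(names(spec)) > n_true_modes)) {
      stop("effect_spec refers to a mode beyond n_true_modes = ", n_true_modes)
    }
  }
  status_probs <- status_probs / sum(status_probs)
  stopifnot(all(status_probs >= 0), all(status_probs <= 1))
  structure(
    list(
      n_participants = n_participants, male_fraction = male_fraction,
      n_true_modes = n_true_modes, eigen_decay = eigen_decay,
      eigenvalues = eigenvalues, landmark_noise_sd = landmark_noise_sd,
      max_rotation_deg = max_rotation_deg, scale_range = scale_range,
      translation_mm = translation_mm, effect_spec = effect_spec,
      covariate_effects = covariate_effects,
      random_effect_sd = random_effect_sd, baseline_logit = baseline_logit,
      kl_positive_prob = kl_positive_prob, status_probs = status_probs,
      seed = seed
    ),
    class = "generator_config"
  )
}

## spectrum: lambda_j = c * j^-gamma with c fixed so that the RMS
## per-landmark displacement of mode 1 is 2 mm: sqrt(lambda_1 / 82) = 2
generator_eigenvalues <- function(cfg, n_points = 82) {
  if (!is.null(cfg$eigenvalues)) return(cfg$eigenvalues)
  c0 <- 4 * n_points
  c0 * seq_len(cfg$n_true_modes)^(-cfg$eigen_decay)
}

#' Simulate SHOMRI cartilage and labral subregion grades
#'
#' Generates the 10 cartilage subregion grades (0-2) and 4 labral subregion
#' grades (0-5) consistent with a given pair of binary outcomes, so that
#' the grades round-trip exactly through [cartilage_defect_present()] and
#' [labral_tear_present()]: a hip with a cartilage defect receives grade
#' >= 1 in at least one cartilage subregion (otherwise all zeros); a hip
#' with a labral tear receives grade >= 2 in at least one labral subregion
#' (otherwise grades 0-1, fraying at most).
#'
#' @param outcome_cartilage,outcome_labral Logical outcome flags.
#' @param seed Optional integer seed for a self-contained draw.
#' @return A list with integer vectors `cartilage` (length 10) and
#'   `labral` (length 4).
#' @export
simulate_shomri <- function(outcome_cartilage, outcome_labral, seed = NULL) {
  with_seed(seed, {
    cart <- integer(10)
    if (isTRUE(outcome_cartilage)) {
      n_pos <- 1 + stats::rbinom(1, 3, 0.3)
      idx <- sample.int(10, n_pos)
      cart[idx] <- sample(1:2, n_pos, replace = TRUE)
    }
    lab <- sample(0:1, 4, replace = TRUE)
    if (isTRUE(outcome_labral)) {
      torn <- stats::runif(4) < 0.35
      if (!any(torn)) torn[sample.int(4, 1)] <- TRUE
      lab[torn] <- sample(2:5, sum(torn), replace = TRUE)
    }
    list(cartilage = cart, labral = lab)
  })
}

#' Simulate a landmark cohort with clinical table and ground truth
#'
#' Generates the full synthetic study: per participant a sex, age, BMI,
#' symptomatic status and a shared logit random effect; per hip true mode
#' scores, an 82-point landmark configuration (template + low-rank smooth
#' deformation + iid landmark noise, left hips mirrored, then a random
#' similarity nuisance transform), a KL grade, binary cartilage/labral
#' outcomes drawn from a logistic model with per-mode effects and covariate
#' terms, and SHOMRI subregion grades consistent with those outcomes.
#'
#' Ages are truncated normal (men 26 +/- 4 on 18-50, women 25 +/- 4), BMI
#' normal (men 24.5 +/- 2.5, women 22.7 +/- 2.5). Covariates enter the
#' outcome model centred at these sex-specific means, so `baseline_logit`
#' is the logit prevalence for an average asymptomatic hip at zero mode
#' scores. Symptomatic status is assigned per participant: a participant is
#' symptomatic with probability `symptomatic + other`; within such
#' participants both hips are symptomatic or one is symptomatic and the
#' contralateral is "other", mixing so the hip-level marginals match
#' `status_probs`.
#'
#' @param cfg A [generator_config()].
#' @return A list with:
#'   \describe{
#'     \item{landmarks}{named list of `hip_landmarks` objects, one per hip}
#'     \item{clinical}{data.frame, one row per hip (see [read_hip_table()]
#'       for the column contract)}
#'     \item{truth}{ground truth: per-sex mode bases and templates,
#'       eigenvalues, per-hip true scores, per-participant random effects,
#'       the effect specification and the seed}
#'   }
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  with_seed(cfg$seed, {
    templates <- list(
      male = make_template("male"),
      female = make_template("female")
    )
    basis_seed <- sample.int(.Machine$integer.max, 2)
    bases <- list(
      male = make_mode_basis(templates$male, cfg$n_true_modes,
        seed = basis_seed[1]
      ),
      female = make_mode_basis(templates$female, cfg$n_true_modes,
        seed = basis_seed[2]
      )
    )
    lambda <- generator_eigenvalues(cfg)

    n <- cfg$n_participants
    sexes <- ifelse(stats::runif(n) < cfg$male_fraction, "male", "female")
    age_mu <- ifelse(sexes == "male", 26, 25)
    bmi_mu <- ifelse(sexes == "male", 24.5, 22.7)
    age <- rtruncnorm(n, age_mu, 4, 18, 50)
    bmi <- stats::rnorm(n, bmi_mu, 2.5)
    u <- stats::rnorm(n, 0, cfg$random_effect_sd)

    ## participant-level status: P(symptomatic participant) = P(sym hip) +
    ## P(other hip); among them both hips symptomatic with probability q
    ## chosen so hip-level marginals match status_probs
    p_sym_part <- cfg$status_probs[["symptomatic"]] + cfg$status_probs[["other"]]
    frac_sym_hip <- if (p_sym_part > 0) {
      cfg$status_probs[["symptomatic"]] / p_sym_part
    } else {
      0
    }
    q_both <- max(0, min(1, 2 * frac_sym_hip - 1))
    part_sym <- stats::runif(n) < p_sym_part

    beta_cart <- effect_vector(cfg$effect_spec$cartilage, cfg$n_true_modes)
    beta_lab <- effect_vector(cfg$effect_spec$labral, cfg$n_true_modes)
    ce <- cfg$covariate_effects

    landmarks <- vector("list", 2 * n)
    rows <- vector("list", 2 * n)
    scores <- matrix(NA_real_, 2 * n, cfg$n_true_modes)
    hip_ids <- character(2 * n)
    k <- 0L

    for (i in seq_len(n)) {
      pid <- sprintf("P%03d", i)
      sex <- sexes[i]
      tpl <- templates[[sex]]
      basis <- bases[[sex]]

      if (part_sym[i]) {
        if (stats::runif(1) < q_both) {
          status <- c("symptomatic", "symptomatic")
        } else {
          status <- sample(c("symptomatic", "other"))
        }
      } else {
        status <- c("asymptomatic", "asymptomatic")
      }

      for (s in 1:2) {
        side <- c("right", "left")[s]
        k <- k + 1L
        z <- stats::rnorm(cfg$n_true_modes)
        scores[k, ] <- z
        flat <- flatten_points(tpl$points) +
          as.vector(basis %*% (sqrt(lambda) * z))
        pts <- unflatten_points(flat)
        pts <- pts + matrix(
          stats::rnorm(length(pts), 0, cfg$landmark_noise_sd),
          ncol = 2
        )
        if (side == "left") pts[, 1] <- -pts[, 1]
        pts <- apply_similarity(
          pts,
          angle_deg = stats::runif(1, -cfg$max_rotation_deg, cfg$max_rotation_deg),
          scale = stats::runif(1, cfg$scale_range[1], cfg$scale_range[2]),
          translation = stats::runif(2, -cfg$translation_mm, cfg$translation_mm)
        )
        hip_id <- paste0(pid, "_", side)
        hip_ids[k] <- hip_id
        landmarks[[k]] <- hip_landmarks(
          points = pts, hip_id = hip_id, participant_id = pid,
          side = side, sex = sex
        )

        st_sym <- as.numeric(status[s] == "symptomatic")
        st_oth <- as.numeric(status[s] == "other")
        eta_cov <- ce[["age"]] * (age[i] - age_mu[i]) +
          ce[["bmi"]] * (bmi[i] - bmi_mu[i]) +
          ce[["symptomatic"]] * st_sym + ce[["other"]] * st_oth + u[i]
        y_cart <- stats::runif(1) < stats::plogis(
          cfg$baseline_logit[["cartilage"]] + sum(beta_cart * z) + eta_cov
        )
        y_lab <- stats::runif(1) < stats::plogis(
          cfg$baseline_logit[["labral"]] + sum(beta_lab * z) + eta_cov
        )
        kl <- if (stats::runif(1) < cfg$kl_positive_prob) sample(1:2, 1) else 0L
        grades <- simulate_shomri(y_cart, y_lab)

        row <- data.frame(
          participant_id = pid, side = side, sex = sex,
          age = age[i], bmi = bmi[i], symptomatic_status = status[s],
          kl_grade = kl, stringsAsFactors = FALSE
        )
        row[paste0("cartilage_", 1:10)] <- as.list(grades$cartilage)
        row[paste0("labral_", 1:4)] <- as.list(grades$labral)
        rows[[k]] <- row
      }
    }

    clinical <- do.call(rbind, rows)
    rownames(clinical) <- NULL
    names(landmarks) <- hip_ids
    rownames(scores) <- hip_ids

    list(
      landmarks = landmarks,
      clinical = clinical,
      truth = list(
        templates = templates, mode_basis = bases, eigenvalues = lambda,
        scores = scores, random_effects = stats::setNames(u, sprintf("P%03d", seq_len(n))),
        effect_spec = cfg$effect_spec, seed = cfg$seed,
        basis_seeds = basis_seed
      )
    )
  })
}

## expand a named sparse effect vector ("12" = log(1.34)) to length J
effect_vector <- function(spec, n_modes) {
  beta <- numeric(n_modes)
  if (length(spec)) {
    idx <- as.integer(names(spec))
    stopifnot(all(idx >= 1), all(idx <= n_modes))
    beta[idx] <- spec
  }
  beta
}

rtruncnorm <- function(n, mean, sd, lo, hi) {
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < lo | out > hi)
  while (length(bad)) {
    out[bad] <- stats::rnorm(length(bad), mean[bad], sd)
    bad <- bad[out[bad] < lo | out[bad] > hi]
  }
  out
}

## rotate (counter-clockwise, degrees), scale about the origin, translate
apply_similarity <- function(points, angle_deg = 0, scale = 1,
                             translation = c(0, 0)) {
  th <- angle_deg * pi / 180
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  out <- scale * (points %*% t(rot))
  out[, 1] <- out[, 1] + translation[1]
  out[, 2] <- out[, 2] + translation[2]
  colnames(out) <- c("x", "y")
  out
}

#' Write a simulated cohort to disk
#'
#' Writes one `.pts` file per hip (named `<participant>_<side>.pts`, with a
#' JSON metadata sidecar), the clinical table as CSV, the ground truth
#' (bases, eigenvalues, scores) as plain CSV files, and the generator
#' configuration as JSON.
#'
#' @param cohort Result of [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @param cfg The [generator_config()] used, echoed to `config.json`.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, cfg = NULL) {
  lm_dir <- file.path(dir, "landmarks")
  dir.create(lm_dir, recursive = TRUE, showWarnings = FALSE)
  for (lm in cohort$landmarks) {
    write_points_file(lm, file.path(lm_dir, paste0(lm$hip_id, ".pts")))
  }
  write_hip_table(cohort$clinical, file.path(dir, "clinical.csv"))
  tr_dir <- file.path(dir, "truth")
  dir.create(tr_dir, showWarnings = FALSE)
  for (sex in names(cohort$truth$mode_basis)) {
    utils::write.csv(
      cohort$truth$mode_basis[[sex]],
      file.path(tr_dir, paste0("mode_basis_", sex, ".csv")),
      row.names = FALSE
    )
  }
  utils::write.csv(
    data.frame(mode = seq_along(cohort$truth$eigenvalues),
               eigenvalue = cohort$truth$eigenvalues),
    file.path(tr_dir, "eigenvalues.csv"), row.names = FALSE
  )
  utils::write.csv(
    data.frame(hip_id = rownames(cohort$truth$scores), cohort$truth$scores),
    file.path(tr_dir, "true_scores.csv"), row.names = FALSE
  )
  if (!is.null(cfg)) {
    jsonlite::write_json(
      unclass(cfg)[setdiff(names(cfg), "eigenvalues")],
      file.path(dir, "config.json"),
      auto_unbox = TRUE, digits = NA
    )
  }
  invisible(dir)
}
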