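#' Configuration for the end-to-end analysis pipeline
#'
#' Either a generator configuration (synthetic study) or input paths (a
#' directory of `.pts` landmark files plus a clinical CSV) must be given.
#'
#' @param out_dir Output directory for the result bundle.
#' @param generator Optional [generator_config()]; when present the cohort
#'   is simulated instead of read from disk.
#' @param landmark_dir Directory of `.pts` files (one per hip).
#' @param clinical_table Path to the clinical CSV (see [read_hip_table()]).
#' @param variance_threshold Mode-inclusion threshold on the variance
#'   fraction (default 0.01, i.e. at least 1.00% of total shape variation).
#' @param working Working correlation for the association models.
#' @param visualization_sds Signed SDs at which mode shapes are written
#'   (default `c(-3, 3)`).
#' @param seed Seed echoed into the manifest (the generator carries its
#'   own seed).
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, generator = NULL, landmark_dir = NULL,
                            clinical_table = NULL, variance_threshold = 0.01,
                            working = "exchangeable",
                            visualization_sds = c(-3, 3), seed = 1) {
  stopifnot(variance_threshold > 0, variance_threshold < 1)
  if (is.null(generator) && (is.null(landmark_dir) || is.null(clinical_table))) {
    stop("pipeline needs either a generator config or landmark_dir + clinical_table")
  }
  structure(
    list(out_dir = out_dir, generator = generator,
         landmark_dir = landmark_dir, clinical_table = clinical_table,
         variance_threshold = variance_threshold, working = working,
         visualization_sds = visualization_sds, seed = seed),
    class = "pipeline_config"
  )
}

#' Run the full shape-association analysis
#'
#' Executes the study stages in order: load (or simulate) and validate the
#' cohort; exclude hips with KL grade > 0; mirror left hips into the
#' right-hip frame; split by sex; Procrustes-align and fit a PCA shape
#' model per sex; standardize scores and select modes explaining at least
#' the threshold fraction of variation; dichotomize SHOMRI grades into the
#' two binary outcomes; run the per-mode GEE association scan per sex and
#' outcome; and write the output bundle: per-sex variance tables,
#' association tables, a cohort summary, mean +/- k SD mode shapes as
#' `.pts` files, and a JSON run manifest (config echo, convergence flags,
#' warnings). Any stage error aborts with a stage-labelled message and
#' removes partial outputs.
#'
#' @param cfg A [pipeline_config()].
#' @return Invisibly, a list with the per-sex models, alignments, scan
#'   tables, the filtered clinical table and the manifest.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  out_dir <- cfg$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  created <- character(0)
  note <- function(path) {
    created <<- c(created, path)
    path
  }
  warnings_log <- character(0)
  stage <- "setup"
  result <- tryCatch(
    withCallingHandlers(
      {
        stage <- "load"
        if (!is.null(cfg$generator)) {
          cohort <- simulate_cohort(cfg$generator)
          landmarks <- cohort$landmarks
          clinical <- validate_hip_table(cohort$clinical)
        } else {
          files <- sort(list.files(cfg$landmark_dir, pattern = "\\.pts$",
                                   full.names = TRUE))
          if (!length(files)) stop("no .pts files in ", cfg$landmark_dir)
          landmarks <- lapply(files, read_points_file)
          names(landmarks) <- vapply(landmarks, `[[`, "", "hip_id")
          clinical <- read_hip_table(cfg$clinical_table)
        }
        clinical$hip_id <- paste0(clinical$participant_id, "_", clinical$side)
        missing_lm <- setdiff(clinical$hip_id, names(landmarks))
        if (length(missing_lm)) {
          stop("no landmark file for hip(s): ",
               paste(utils::head(missing_lm, 5), collapse = ", "))
        }

        stage <- "exclude_kl"
        excl <- exclude_kl(clinical)
        clinical <- excl$retained
        landmarks <- landmarks[clinical$hip_id]

        stage <- "outcomes"
        clinical <- derive_outcomes(clinical)

        stage <- "mirror"
        landmarks <- lapply(landmarks, function(lm) {
          if (lm$side == "left") mirror_left(lm) else lm
        })

        stage <- "per_sex_models"
        per_sex <- list()
        for (sex in c("male", "female")) {
          rows <- clinical$sex == sex
          if (sum(rows) < 3) next
          lm_sex <- landmarks[clinical$hip_id[rows]]
          gpa <- generalized_procrustes(lm_sex)
          model <- fit_shape_model(gpa, sex = sex)
          selected <- select_modes(model, cfg$variance_threshold)
          scan <- run_association_scan(
            scores = model$standardized_scores,
            outcomes = list(
              cartilage_defect = clinical$cartilage_defect_present[rows],
              labral_tear = clinical$labral_tear_present[rows]
            ),
            covariates = clinical[rows, c("age", "bmi", "symptomatic_status")],
            cluster_ids = clinical$participant_id[rows],
            selected_modes = selected,
            working = cfg$working
          )
          per_sex[[sex]] <- list(
            gpa = gpa, model = model, selected = selected, scan = scan
          )
        }
        if (!length(per_sex)) stop("no sex stratum has at least 3 hips")

        stage <- "write_outputs"
        summ <- cohort_summary(clinical)
        utils::write.csv(summ$participants,
          note(file.path(out_dir, "cohort_summary_participants.csv")),
          row.names = FALSE)
        utils::write.csv(summ$hips,
          note(file.path(out_dir, "cohort_summary_hips.csv")),
          row.names = FALSE)
        shape_dir <- file.path(out_dir, "mode_shapes")
        for (sex in names(per_sex)) {
          ps <- per_sex[[sex]]
          utils::write.csv(variance_table(ps$model),
            note(file.path(out_dir, paste0("variance_", sex, ".csv"))),
            row.names = FALSE)
          utils::write.csv(ps$scan,
            note(file.path(out_dir, paste0("associations_", sex, ".csv"))),
            row.names = FALSE)
          for (m in ps$selected) {
            for (k in cfg$visualization_sds) {
              tag <- sprintf("%s_mode%02d_%s%dsd", sex, m,
                             if (k < 0) "minus" else "plus", abs(k))
              lm <- hip_landmarks(mode_shape_at(ps$model, m, k),
                                  participant_id = tag, side = "right",
                                  sex = sex, hip_id = tag)
              note(write_points_file(
                lm, file.path(shape_dir, paste0(tag, ".pts"))
              ))
            }
          }
        }

        stage <- "manifest"
        manifest <- list(
          config = list(
            variance_threshold = cfg$variance_threshold,
            working = cfg$working,
            visualization_sds = cfg$visualization_sds,
            seed = cfg$seed,
            generator_seed = if (!is.null(cfg$generator)) cfg$generator$seed,
            simulated = !is.null(cfg$generator)
          ),
          package_version = as.character(utils::packageVersion("hipshapes")),
          n_hips = nrow(clinical),
          n_excluded_kl = excl$n_excluded,
          strata = lapply(per_sex, function(ps) list(
            n_hips = ps$model$n_shapes,
            gpa_iterations = ps$gpa$iterations,
            gpa_converged = ps$gpa$converged,
            selected_modes = ps$selected,
            bonferroni_alpha = attr(ps$scan, "bonferroni_alpha")
          )),
          empty_strata = setdiff(c("male", "female"), names(per_sex)),
          warnings = warnings_log
        )
        jsonlite::write_json(manifest,
          note(file.path(out_dir, "manifest.json")),
          auto_unbox = TRUE, digits = NA, pretty = TRUE)

        list(per_sex = per_sex, clinical = clinical, manifest = manifest,
             n_excluded_kl = excl$n_excluded)
      },
      warning = function(w) {
        warnings_log <<- c(warnings_log, conditionMessage(w))
        invokeRestart("muffleWarning")
      }
    ),
    error = function(e) {
      unlink(created)
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    }
  )
  invisible(result)
}
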