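#' Classify a hip's symptomatic status
#'
#' A hip is *symptomatic* if the participant reported hip and/or groin
#' pain for more than 6 months AND the hip had a positive
#' flexion-adduction-internal-rotation (FADIR) provocation test. A
#' non-symptomatic hip of a participant who has at least one symptomatic
#' hip is an *other* hip (the asymptomatic contralateral side of a
#' symptomatic participant); all remaining hips are *asymptomatic*.
#'
#' @param pain_over_6mo Pain for more than six months? (logical,
#'   vectorised)
#' @param fadir_positive Positive FADIR test? (logical, vectorised)
#' @param participant_has_symptomatic_hip Does the participant have at
#'   least one symptomatic hip? (logical, vectorised)
#' @return Character vector: `"symptomatic"`, `"other"` or
#'   `"asymptomatic"`.
#' @export
classify_symptomatic_status <- function(pain_over_6mo, fadir_positive,
                                        participant_has_symptomatic_hip) {
  ifelse(
    pain_over_6mo & fadir_positive, "symptomatic",
    ifelse(participant_has_symptomatic_hip, "other", "asymptomatic")
  )
}

#' Exclude hips with radiographic osteoarthritis
#'
#' Removes hips with Kellgren-Lawrence grade > 0 (doubtful osteoarthritis
#' or worse). Exclusion is per hip: a participant's contralateral hip with
#' KL grade 0 remains in the cohort.
#'
#' @param records Hip table (data.frame with a `kl_grade` column).
#' @return A list with `retained` (the filtered data.frame) and
#'   `n_excluded`.
#' @export
exclude_kl <- function(records) {
  if (!"kl_grade" %in% names(records) || anyNA(records$kl_grade)) {
    stop("kl_grade must be present and non-missing for every hip")
  }
  keep <- records$kl_grade == 0
  list(retained = records[keep, , drop = FALSE], n_excluded = sum(!keep))
}

#' Dichotomize SHOMRI cartilage grades
#'
#' A cartilage defect is present if any cartilage loss (SHOMRI grade >= 1)
#' is evident in at least one of the 10 acetabular or femoral subregions.
#'
#' @param grades Integer vector of 10 grades in 0-2, or a matrix/data.frame
#'   with 10 columns (one row per hip).
#' @return Logical flag (or vector, one per row).
#' @export
cartilage_defect_present <- function(grades) {
  dichotomize_grades(grades, n = 10, max_grade = 2, threshold = 1,
                     what = "cartilage")
}

#' Dichotomize SHOMRI labral grades
#'
#' A labral tear is present if a SHOMRI grade >= 2 lesion (simple tear or
#' worse) is found in any of the 4 labral subregions; grade 1 (abnormal
#' signal or fraying) is below the threshold.
#'
#' @param grades Integer vector of 4 grades in 0-5, or a matrix/data.frame
#'   with 4 columns (one row per hip).
#' @return Logical flag (or vector, one per row).
#' @export
labral_tear_present <- function(grades) {
  dichotomize_grades(grades, n = 4, max_grade = 5, threshold = 2,
                     what = "labral")
}

dichotomize_grades <- function(grades, n, max_grade, threshold, what) {
  if (is.data.frame(grades)) grades <- as.matrix(grades)
  if (!is.matrix(grades)) grades <- matrix(grades, nrow = 1)
  if (ncol(grades) != n) {
    stop("expected ", n, " ", what, " grades, got ", ncol(grades))
  }
  if (anyNA(grades) || any(grades < 0 | grades > max_grade |
                           grades != round(grades))) {
    stop(what, " grades must be integers in [0, ", max_grade, "]")
  }
  out <- apply(grades, 1, function(g) any(g >= threshold))
  unname(out)
}

#' Derive binary outcome flags for a hip table
#'
#' Applies the SHOMRI dichotomization rules to the `cartilage_*` and
#' `labral_*` columns of a hip table.
#'
#' @param records Hip table (see [read_hip_table()]).
#' @return The table with logical columns `cartilage_defect_present` and
#'   `labral_tear_present` appended.
#' @export
derive_outcomes <- function(records) {
  records$cartilage_defect_present <-
    cartilage_defect_present(records[paste0("cartilage_", 1:10)])
  records$labral_tear_present <-
    labral_tear_present(records[paste0("labral_", 1:4)])
  records
}

#' Summarise the cohort, Table-1 style
#'
#' Per-sex participant counts with median [Q1-Q3] for age and BMI
#' (linear-interpolation, type-7 quantiles), and per-sex hip counts with
#' one-decimal percentages by symptomatic status and binary outcome.
#'
#' @param records Hip table; outcome columns are derived if absent.
#' @return A list with `participants` and `hips` data.frames.
#' @export
cohort_summary <- function(records) {
  if (nrow(records) == 0) stop("cannot summarise an empty cohort")
  if (!"cartilage_defect_present" %in% names(records)) {
    records <- derive_outcomes(records)
  }
  pct <- function(k, n) round(100 * k / n, 1)

  part <- unique(records[c("participant_id", "sex", "age", "bmi")])
  participants <- do.call(rbind, lapply(split(part, part$sex), function(d) {
    qa <- stats::quantile(d$age, c(.25, .5, .75), type = 7)
    qb <- stats::quantile(d$bmi, c(.25, .5, .75), type = 7)
    data.frame(
      sex = d$sex[1], n_participants = nrow(d),
      age_median = qa[[2]], age_q1 = qa[[1]], age_q3 = qa[[3]],
      bmi_median = qb[[2]], bmi_q1 = qb[[1]], bmi_q3 = qb[[3]]
    )
  }))

  hips <- do.call(rbind, lapply(split(records, records$sex), function(d) {
    n <- nrow(d)
    data.frame(
      sex = d$sex[1], n_hips = n,
      n_symptomatic = sum(d$symptomatic_status == "symptomatic"),
      pct_symptomatic = pct(sum(d$symptomatic_status == "symptomatic"), n),
      n_other = sum(d$symptomatic_status == "other"),
      pct_other = pct(sum(d$symptomatic_status == "other"), n),
      n_asymptomatic = sum(d$symptomatic_status == "asymptomatic"),
      pct_asymptomatic = pct(sum(d$symptomatic_status == "asymptomatic"), n),
      n_cartilage_defect = sum(d$cartilage_defect_present),
      pct_cartilage_defect = pct(sum(d$cartilage_defect_present), n),
      n_labral_tear = sum(d$labral_tear_present),
      pct_labral_tear = pct(sum(d$labral_tear_present), n)
    )
  }))
  rownames(participants) <- rownames(hips) <- NULL
  list(participants = participants, hips = hips)
}
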