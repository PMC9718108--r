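#!/usr/bin/env Rscript
# Stage 2: Procrustes alignment and per-sex shape models.
#
# Reads the cohort from stage 1, excludes hips with KL grade > 0, mirrors
# left hips into the right-hip frame, aligns each sex separately with
# generalized Procrustes analysis, fits the PCA shape model, and keeps the
# modes explaining at least 1.00% of total shape variation. Writes the
# variance tables to results/ and the standardized scores of the selected
# modes to scratch/analysis/ for the association stage.

suppressPackageStartupMessages(library(hipshapes))

data_dir <- "scratch/analysis/cohort"
clinical <- read_hip_table(file.path(data_dir, "clinical.csv"))
clinical$hip_id <- paste0(clinical$participant_id, "_", clinical$side)

excl <- exclude_kl(clinical)
clinical <- excl$retained
cat("KL exclusion: removed", excl$n_excluded, "hips,",
    nrow(clinical), "remain\n")

dir.create("results", showWarnings = FALSE)
for (sex in c("male", "female")) {
  sub <- clinical[clinical$sex == sex, ]
  landmarks <- lapply(sub$hip_id, function(id) {
    lm <- read_points_file(file.path(data_dir, "landmarks",
                                     paste0(id, ".pts")))
    if (lm$side == "left") mirror_left(lm) else lm
  })
  gpa <- generalized_procrustes(landmarks)
  model <- fit_shape_model(gpa, sex = sex)
  selected <- select_modes(model)
  vt <- variance_table(model)

  cat(sprintf(
    "%s: %d hips, GPA converged in %d iterations; %d modes at >= 1.00%%, together %.1f%% of variation\n",
    sex, nrow(sub), gpa$iterations, length(selected),
    100 * sum(model$variance_fraction[selected])
  ))

  write.csv(vt, file.path("results", paste0("variance_", sex, ".csv")),
            row.names = FALSE)
  scores <- data.frame(hip_id = sub$hip_id,
                       model$standardized_scores[, selected, drop = FALSE])
  write.csv(scores,
            file.path("scratch/analysis", paste0("scores_", sex, ".csv")),
            row.names = FALSE)
}
write.csv(clinical, "scratch/analysis/clinical_included.csv",
          row.names = FALSE)
cat("variance tables in results/, scores in scratch/analysis/\n")
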