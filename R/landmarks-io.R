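#' Landmark configuration for a single hip
#'
#' One hip's 82 ordered 2-D landmark points (millimetres, y-up) with
#' identifying metadata.
#'
#' @param points An `82 x 2` numeric matrix of finite coordinates.
#' @param hip_id Unique hip identifier (default `<participant>_<side>`).
#' @param participant_id Participant identifier.
#' @param side `"left"` or `"right"`.
#' @param sex `"male"`, `"female"`, or `NA` if unknown.
#' @return An object of class `hip_landmarks`.
#' @export
hip_landmarks <- function(points, participant_id, side,
                          sex = NA_character_,
                          hip_id = paste0(participant_id, "_", side)) {
  points <- as.matrix(points)
  if (nrow(points) != 82 || ncol(points) != 2) {
    stop("wrong point count: expected 82 x 2 points, got ",
         nrow(points), " x ", ncol(points))
  }
  if (!all(is.finite(points))) stop("non-finite coordinate in landmark set")
  side <- match.arg(side, c("left", "right"))
  if (!is.na(sex)) sex <- match.arg(sex, c("male", "female"))
  colnames(points) <- c("x", "y")
  structure(
    list(points = points, hip_id = hip_id, participant_id = participant_id,
         side = side, sex = sex),
    class = "hip_landmarks"
  )
}

#' @export
print.hip_landmarks <- function(x, ...) {
  cat("<hip_landmarks>", x$hip_id, "-", x$side, "hip,",
      ifelse(is.na(x$sex), "sex unknown", x$sex), "\n")
  cat("  82 points, centroid (",
      paste(sprintf("%.2f", colMeans(x$points)), collapse = ", "),
      ") mm\n", sep = "")
  invisible(x)
}

#' Read and write landmark point files
#'
#' The point-file dialect is plain text: header lines `version: 1` and
#' `n_points: 82`, an opening `{`, 82 whitespace-separated `x y` lines
#' (millimetres, y-up), and a closing `}`. Metadata (participant, side,
#' sex) is taken from a JSON sidecar `<stem>.meta.json` when present,
#' otherwise parsed from a `<participant>_<side>.pts` filename.
#'
#' @param path Path to a `.pts` file.
#' @return [read_points_file()]: a [hip_landmarks()] object.
#' @export
read_points_file <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  if (length(lines) < 4 || !grepl("^version:\\s*1$", lines[1])) {
    stop("malformed header: expected 'version: 1' on line 1 of ", path)
  }
  m <- regmatches(lines[2], regexec("^n_points:\\s*(\\d+)$", lines[2]))[[1]]
  if (length(m) != 2) {
    stop("malformed header: expected 'n_points: <count>' on line 2 of ", path)
  }
  n_declared <- as.integer(m[2])
  if (n_declared != 82) {
    stop("wrong point count: file declares n_points: ", n_declared,
         ", expected 82")
  }
  if (lines[3] != "{" || lines[length(lines)] != "}") {
    stop("malformed body: expected '{' ... '}' delimiters in ", path)
  }
  body <- lines[4:(length(lines) - 1)]
  if (length(body) != n_declared) {
    stop("wrong point count: ", length(body), " coordinate lines, declared ",
         n_declared)
  }
  coords <- strsplit(body, "\\s+")
  if (any(lengths(coords) != 2)) {
    stop("malformed coordinate line: expected 'x y' pairs in ", path)
  }
  vals <- suppressWarnings(as.numeric(unlist(coords)))
  if (anyNA(vals)) stop("non-numeric coordinate in ", path)
  pts <- matrix(vals, ncol = 2, byrow = TRUE)

  meta <- read_points_metadata(path)
  hip_landmarks(pts, participant_id = meta$participant_id, side = meta$side,
                sex = meta$sex, hip_id = meta$hip_id)
}

read_points_metadata <- function(path) {
  stem <- sub("\\.pts$", "", path)
  sidecar <- paste0(stem, ".meta.json")
  base <- basename(stem)
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    return(list(
      participant_id = meta$participant_id %||% base,
      side = meta$side,
      sex = meta$sex %||% NA_character_,
      hip_id = meta$hip_id %||% base
    ))
  }
  m <- regmatches(base, regexec("^(.+)_(left|right)$", base))[[1]]
  if (length(m) != 3) {
    stop("cannot determine metadata for ", path,
         ": no sidecar and filename is not '<participant>_<side>.pts'")
  }
  list(participant_id = m[2], side = m[3], sex = NA_character_, hip_id = base)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname read_points_file
#' @param config A [hip_landmarks()] object.
#' @param sidecar Write the JSON metadata sidecar too? (default `TRUE`).
#' @return [write_points_file()]: `path`, invisibly.
#' @export
write_points_file <- function(config, path, sidecar = TRUE) {
  stopifnot(inherits(config, "hip_landmarks"))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  if (file.exists(path)) {
    message("overwriting existing points file: ", path)
  }
  lines <- c(
    "version: 1",
    sprintf("n_points: %d", nrow(config$points)),
    "{",
    sprintf("%.12g %.12g", config$points[, 1], config$points[, 2]),
    "}"
  )
  writeLines(lines, path)
  if (sidecar) {
    jsonlite::write_json(
      list(
        hip_id = config$hip_id, participant_id = config$participant_id,
        side = config$side, sex = config$sex
      ),
      paste0(sub("\\.pts$", "", path), ".meta.json"),
      auto_unbox = TRUE, null = "null", na = "null"
    )
  }
  invisible(path)
}

hip_table_columns <- c(
  "participant_id", "side", "sex", "age", "bmi", "symptomatic_status",
  "kl_grade", paste0("cartilage_", 1:10), paste0("labral_", 1:4)
)

#' Read and write the per-hip clinical table
#'
#' The clinical table is a CSV with one row per hip and columns
#' `participant_id`, `side`, `sex`, `age`, `bmi`, `symptomatic_status`
#' (`symptomatic` | `other` | `asymptomatic`), `kl_grade` (0-4),
#' `cartilage_1` .. `cartilage_10` (SHOMRI cartilage grades 0-2) and
#' `labral_1` .. `labral_4` (SHOMRI labral grades 0-5). Reading validates
#' every range and never coerces out-of-range values.
#'
#' @param path CSV path.
#' @return [read_hip_table()]: a validated data.frame (possibly 0 rows).
#' @export
read_hip_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_hip_table(df)
}

#' @rdname read_hip_table
#' @param records A data.frame of hip records.
#' @export
write_hip_table <- function(records, path) {
  records <- validate_hip_table(records)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

validate_hip_table <- function(df) {
  missing_cols <- setdiff(hip_table_columns, names(df))
  if (length(missing_cols)) {
    stop("missing column(s) in hip table: ", paste(missing_cols, collapse = ", "))
  }
  df <- df[hip_table_columns]
  if (nrow(df) == 0) return(df)
  check_levels <- function(x, levels, what) {
    bad <- !x %in% levels
    if (any(bad)) {
      stop("unknown ", what, " value(s): ",
           paste(unique(x[bad]), collapse = ", "))
    }
  }
  check_levels(df$side, c("left", "right"), "side")
  check_levels(df$sex, c("male", "female"), "sex")
  check_levels(df$symptomatic_status,
               c("symptomatic", "other", "asymptomatic"), "symptomatic_status")
  check_grade <- function(x, lo, hi, what) {
    if (anyNA(x) || any(x < lo | x > hi | x != round(x))) {
      stop("out-of-range ", what, ": values must be integers in [",
           lo, ", ", hi, "]")
    }
  }
  check_grade(df$kl_grade, 0, 4, "kl_grade")
  for (col in paste0("cartilage_", 1:10)) {
    check_grade(df[[col]], 0, 2, col)
  }
  for (col in paste0("labral_", 1:4)) {
    check_grade(df[[col]], 0, 5, col)
  }
  if (anyNA(df$age) || anyNA(df$bmi)) stop("missing age or bmi value")
  df
}
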