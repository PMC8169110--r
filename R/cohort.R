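#' Longitudinal cohort measurements
#'
#' Per-subject tumor volumes by arm and day. The canonical on-disk form is a
#' CSV with header `arm,subject_id,day,volume_mm3`; per-day summaries use
#' `arm,day,mean_mm3,sd_mm3`.
#'
#' @param df A data frame with columns `arm`, `subject_id`, `day`,
#'   `volume_mm3`.
#' @return A validated data frame of class `cohort_measurements`.
#' @export
cohort_measurements <- function(df) {
  req <- c("arm", "subject_id", "day", "volume_mm3")
  missing <- setdiff(req, names(df))
  if (length(missing) > 0)
    stop("cohort data lacks column(s): ", paste(missing, collapse = ", "))
  if (any(df$volume_mm3 < 0)) stop("tumor volumes must be >= 0")
  if (any(df$day < 0)) stop("measurement days must be >= 0")
  key <- paste(df$arm, df$subject_id, df$day)
  if (anyDuplicated(key))
    stop("duplicate (arm, subject, day) measurement(s)")
  structure(as.data.frame(df[req]),
            class = c("cohort_measurements", "data.frame"))
}

#' @rdname cohort_measurements
#' @param path CSV file path.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE),
    error = function(e) stop("malformed cohort CSV '", path, "': ",
                             conditionMessage(e)))
  cohort_measurements(df)
}

#' @rdname cohort_measurements
#' @param cohort A `cohort_measurements` object.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Per-day arm summaries
#'
#' Mean and standard deviation of tumor volume by arm and day, the level at
#' which the calibration routines fit (population-mean fitting).
#'
#' @param cohort A [cohort_measurements()] data frame.
#' @param arm Optional single arm label to filter on.
#' @return Data frame with columns `arm`, `day`, `mean_mm3`, `sd_mm3`, `n`.
#' @export
arm_means <- function(cohort, arm = NULL) {
  df <- as.data.frame(cohort)
  if (!is.null(arm)) {
    df <- df[df$arm == arm, , drop = FALSE]
    if (nrow(df) == 0) stop("no measurements for arm '", arm, "'")
  }
  agg <- stats::aggregate(volume_mm3 ~ arm + day, data = df,
                          FUN = function(v) c(mean(v), stats::sd(v),
                                              length(v)))
  out <- data.frame(arm = agg$arm, day = agg$day,
                    mean_mm3 = agg$volume_mm3[, 1],
                    sd_mm3 = agg$volume_mm3[, 2],
                    n = agg$volume_mm3[, 3])
  out[order(out$arm, out$day), , drop = FALSE]
}
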