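#' Read and write pattern / sketch CSV files
#'
#' The pattern dialect is a UTF-8 CSV with header
#' `phase,load,thigh,knee,ankle` and one row per phase node: 200 or 201
#' rows for a continuous pattern, 11 rows for a sketch. Readers reject
#' files with the wrong column set.
#'
#' @param p A `gait_pattern` or `discretized_pattern`.
#' @param path File path.
#' @param units Units to tag the object read from disk with.
#' @return Readers return the pattern object; writers the path,
#'   invisibly.
#' @name pattern_io
NULL

pattern_columns <- c("phase", gait_channels())

#' @rdname pattern_io
#' @export
write_pattern_csv <- function(p, path) {
  df <- data.frame(phase = attr(p, "phase"), unclass(p))
  colnames(df) <- pattern_columns
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

read_pattern_df <- function(path) {
  df <- utils::read.csv(path)
  if (!identical(colnames(df), pattern_columns)) {
    stop("expected columns ", paste(pattern_columns, collapse = ","),
         " in ", path, call. = FALSE)
  }
  df
}

#' @rdname pattern_io
#' @export
read_pattern_csv <- function(path, units = c("physical", "normalized")) {
  units <- match.arg(units)
  df <- read_pattern_df(path)
  gait_pattern(as.matrix(df[, gait_channels()]), units = units)
}

#' @rdname pattern_io
#' @export
read_sketch_csv <- function(path, units = c("physical", "normalized")) {
  units <- match.arg(units)
  df <- read_pattern_df(path)
  discretized_pattern(as.matrix(df[, gait_channels()]), units = units)
}

#' Read and write raw-trial CSVs with sidecar metadata
#'
#' Trials are stored as `t,load,thigh,knee,ankle` CSVs plus a JSON
#' sidecar (`<file>.json`) holding the subject weight (kg), mode label
#' and sample period.
#'
#' @param trial A `raw_trial`.
#' @param path CSV path; metadata goes to `paste0(path, ".json")`.
#' @return Readers return the `raw_trial`; writers the path, invisibly.
#' @name trial_io
NULL

#' @rdname trial_io
#' @export
write_trial_csv <- function(trial, path) {
  stopifnot(inherits(trial, "raw_trial"))
  t <- (seq_len(nrow(trial$values)) - 1L) * trial$sample_period
  df <- data.frame(t = t, trial$values)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(weight = trial$weight, mode = trial$mode,
                            sample_period = trial$sample_period),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname trial_io
#' @export
read_trial_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("t", gait_channels())
  if (!identical(colnames(df), need)) {
    stop("expected columns ", paste(need, collapse = ","), " in ", path,
         call. = FALSE)
  }
  meta_path <- paste0(path, ".json")
  if (!file.exists(meta_path)) {
    stop("missing sidecar metadata ", meta_path, call. = FALSE)
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  raw_trial(as.matrix(df[, gait_channels()]),
            sample_period = meta$sample_period %||% SAMPLE_PERIOD,
            weight = meta$weight, mode = meta$mode %||% "lgw")
}

#' Write / read a controller-training time series
#'
#' Columnar CSV `t,load,thigh,knee,ankle,k_knee,b_knee,k_ankle,b_ankle`
#' (the impedance block is omitted when absent).
#'
#' @param ts A `timeseries_gait`.
#' @param path File path.
#' @param units Units tag on read.
#' @return Readers return the `timeseries_gait`; writers the path,
#'   invisibly.
#' @name timeseries_io
NULL

#' @rdname timeseries_io
#' @export
write_timeseries_csv <- function(ts, path) {
  stopifnot(inherits(ts, "timeseries_gait"))
  t <- (seq_len(nrow(ts$values)) - 1L) * ts$sample_period
  df <- data.frame(t = t, ts$values)
  if (!is.null(ts$impedance)) df <- cbind(df, ts$impedance)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname timeseries_io
#' @export
read_timeseries_csv <- function(path, units = c("normalized", "physical")) {
  units <- match.arg(units)
  df <- utils::read.csv(path)
  gait_cols <- gait_channels()
  if (!all(c("t", gait_cols) %in% colnames(df))) {
    stop("missing gait columns in ", path, call. = FALSE)
  }
  imp <- if (all(impedance_channels() %in% colnames(df))) {
    as.matrix(df[, impedance_channels()])
  }
  sp <- if (nrow(df) > 1L) df$t[2] - df$t[1] else SAMPLE_PERIOD
  timeseries_gait(as.matrix(df[, gait_cols]), impedance = imp,
                  sample_period = sp, units = units)
}
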