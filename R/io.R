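# Readers and writers for raw-acceleration CSV (generic 3-column and the
# ActiGraph RAW CSV dialect with its multi-line header), epoch-count CSV and
# intensity-profile CSV.

#' Read raw tri-axial acceleration from CSV
#'
#' Two dialects are understood. The generic dialect has a single header line
#' `x,y,z` or `time,x,y,z`; sampling rate and units come from the `fs` and
#' `units` arguments (or, for a `time` column in seconds, the rate is
#' inferred from the sample spacing). The ActiGraph RAW dialect is detected
#' by its first line starting with `"------------"`; the 10-line header is
#' parsed for the sampling rate (`"... at NN Hz"`) and start date/time, and
#' the three acceleration columns are read in g.
#'
#' @param path CSV file.
#' @param fs sampling rate in Hz; required for the generic dialect without a
#'   time column, ignored (header wins) for the ActiGraph dialect.
#' @param units `"g"` or `"m/s2"` (generic dialect; ActiGraph RAW is in g).
#' @return A [raw_accel()].
#' @export
read_accel_csv <- function(path, fs = NULL, units = "g") {
  first <- readLines(path, n = 1L)
  if (startsWith(first, "------------"))
    return(read_actigraph_raw(path))
  df <- utils::read.csv(path)
  nm <- tolower(names(df))
  if (all(c("x", "y", "z") %in% nm)) {
    x <- df[[which(nm == "x")]]; y <- df[[which(nm == "y")]]
    z <- df[[which(nm == "z")]]
    if (is.null(fs) && "time" %in% nm) {
      tt <- df[[which(nm == "time")]]
      fs <- round(1 / stats::median(diff(tt)), 6)
    }
  } else if (ncol(df) >= 3L) {
    x <- df[[1]]; y <- df[[2]]; z <- df[[3]]
  } else {
    stop_invalid("cannot locate x/y/z columns in ", path)
  }
  if (is.null(fs))
    stop_invalid("sampling rate not in the file header; pass fs explicitly ",
                 "(e.g. fs = 30) or add a 'time' column in seconds")
  raw_accel(x, y, z, fs = fs, units = units)
}

read_actigraph_raw <- function(path) {
  header <- readLines(path, n = 10L)
  rate <- regmatches(header[1],
                     regexpr("at [0-9.]+ *Hz", header[1]))
  if (length(rate) == 0L)
    stop_invalid("ActiGraph header does not state a sampling rate ",
                 "(expected '... at NN Hz ...')")
  fs <- as.numeric(gsub("[^0-9.]", "", rate))
  grab <- function(key) {
    ln <- grep(key, header, value = TRUE)
    if (length(ln)) trimws(sub(paste0(".*", key), "", ln[1])) else NA
  }
  st <- grab("Start Time")
  sd_ <- grab("Start Date")
  start_time <- if (!is.na(st) && !is.na(sd_))
    as.POSIXct(paste(sd_, st), tryFormats = c("%m/%d/%Y %H:%M:%S",
                                              "%Y-%m-%d %H:%M:%S"),
               tz = "UTC") else NULL
  skip <- 10L
  df <- utils::read.csv(path, skip = skip)
  if (ncol(df) < 3L) stop_invalid("ActiGraph RAW file needs 3 data columns")
  raw_accel(df[[1]], df[[2]], df[[3]], fs = fs, units = "g",
            start_time = start_time)
}

#' Write raw acceleration to CSV
#'
#' @param raw a [raw_accel()].
#' @param path output file.
#' @param dialect `"generic"` (header `time,x,y,z`) or `"actigraph"`
#'   (synthetic ActiGraph RAW dialect with a 10-line header; useful as a
#'   fixture for testing the dialect reader).
#' @return `path`, invisibly.
#' @export
write_accel_csv <- function(raw, path, dialect = c("generic", "actigraph")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(raw, "raw_accel"))
  if (dialect == "generic") {
    t <- (seq_along(raw$ax) - 1) / raw$fs
    utils::write.csv(data.frame(time = t, x = raw$ax, y = raw$ay,
                                z = raw$az),
                     path, row.names = FALSE)
    return(invisible(path))
  }
  st <- raw$start_time
  if (is.null(st)) st <- as.POSIXct("2020-01-01 00:00:00", tz = "UTC")
  header <- c(
    sprintf(paste0("------------ Data File Created By Wearcounts Synthetic ",
                   "Writer at %g Hz  Filter Normal ------------"), raw$fs),
    "Serial Number: SYN1A00000000",
    sprintf("Start Time %s", format(st, "%H:%M:%S")),
    sprintf("Start Date %s", format(st, "%m/%d/%Y")),
    "Epoch Period (hh:mm:ss) 00:00:00",
    sprintf("Download Time %s", format(st, "%H:%M:%S")),
    sprintf("Download Date %s", format(st, "%m/%d/%Y")),
    "Current Memory Address: 0",
    "Current Battery Voltage: 4.0     Mode = 12",
    "--------------------------------------------------")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.csv(data.frame(`Accelerometer X` = raw$ax,
                              `Accelerometer Y` = raw$ay,
                              `Accelerometer Z` = raw$az,
                              check.names = FALSE),
                   con, row.names = FALSE)
  invisible(path)
}

#' Write an epoch count series to CSV
#'
#' Columns: `epoch_index,epoch_start_s,sx,sy,sz,vm3`, one row per epoch.
#'
#' @param counts a [count_series()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_counts_csv <- function(counts, path) {
  stopifnot(inherits(counts, "count_series"))
  utils::write.csv(as.data.frame(counts), path, row.names = FALSE)
  invisible(path)
}

#' Read an epoch count series from CSV
#'
#' @param path a CSV written by [write_counts_csv()].
#' @param epoch_s epoch length in seconds; inferred from `epoch_start_s`
#'   when present.
#' @return A [count_series()].
#' @export
read_counts_csv <- function(path, epoch_s = NULL) {
  df <- utils::read.csv(path)
  need <- c("sx", "sy", "sz")
  if (!all(need %in% names(df)))
    stop_invalid("counts CSV must have columns sx, sy, sz")
  if (nrow(df) == 0L) stop_invalid("counts CSV is empty: ", path)
  if (is.null(epoch_s)) {
    epoch_s <- if ("epoch_start_s" %in% names(df) && nrow(df) > 1L)
      df$epoch_start_s[2] - df$epoch_start_s[1] else 1
  }
  count_series(df$sx, df$sy, df$sz, epoch_s = epoch_s)
}

#' Write an intensity profile to CSV
#'
#' The summary (`category,epochs,percent`) and, optionally, the per-epoch /
#' per-window detail (`index,cpm,category`).
#'
#' @param profile an `intensity_profile`.
#' @param path summary CSV file.
#' @param detail_path optional detail CSV file.
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(profile, path, detail_path = NULL) {
  stopifnot(inherits(profile, "intensity_profile"))
  utils::write.csv(profile$summary, path, row.names = FALSE)
  if (!is.null(detail_path))
    utils::write.csv(profile$detail, detail_path, row.names = FALSE)
  invisible(path)
}

#' Write an agreement report to CSV
#'
#' One row of named agreement statistics.
#'
#' @param report an [agreement()] report.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_agreement_csv <- function(report, path) {
  stopifnot(inherits(report, "agreement_report"))
  fields <- c("n", "epoch_s", "pearson_r", "spearman_rho",
              "mean_difference", "loa_low", "loa_high", "n_outside",
              "pct_outside", "relative_difference_pct", "regression_slope",
              "regression_intercept", "regression_r")
  utils::write.csv(as.data.frame(report[fields]), path, row.names = FALSE)
  invisible(path)
}
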