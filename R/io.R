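#' @title File I/O for the ambulatory-HRV pipeline
#' @description
#' All on-disk formats are plain comma-separated text with one header row,
#' decimal points, times in seconds from recording start, and missing values
#' encoded as empty fields (never as zero: zero RMSSD or acceleration is a
#' meaningful physiological value). Four file kinds are exchanged: interbeat
#' intervals, epoch series, calibration phase annotations, and hourly
#' self-reports.
#' @name addhrvr-io
NULL

# Parse a CSV file into a data frame of character columns, reporting the
# 1-based file line of every record so downstream validation can name lines.
read_csv_strict <- function(path, columns) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*$", lines) | seq_along(lines) == 1]
  if (length(lines) == 0) {
    stop(sprintf("%s: empty file (header row required)", path), call. = FALSE)
  }
  header <- trimws(strsplit(lines[1], ",", fixed = TRUE)[[1]])
  missing_cols <- setdiff(columns, header)
  if (length(missing_cols)) {
    stop(sprintf("%s: header lacks column(s): %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  body <- lines[-1]
  n <- length(body)
  cells <- vector("list", n)
  for (i in seq_len(n)) {
    row <- strsplit(body[i], ",", fixed = TRUE)[[1]]
    # trailing empty field is dropped by strsplit; restore it
    length(row) <- length(header)
    row[is.na(row)] <- ""
    if (length(row) != length(header)) {
      stop(sprintf("%s: line %d: expected %d fields, found %d",
                   path, i + 1, length(header), length(row)), call. = FALSE)
    }
    cells[[i]] <- trimws(row)
  }
  mat <- if (n) do.call(rbind, cells) else
    matrix(character(0), 0, length(header))
  colnames(mat) <- header
  out <- as.data.frame(mat[, columns, drop = FALSE],
                       stringsAsFactors = FALSE)
  attr(out, "file_lines") <- if (n) seq_len(n) + 1L else integer(0)
  attr(out, "path") <- path
  out
}

# Convert a character column to numeric, naming the file line on failure.
# Empty fields become NA (missing), which callers may forbid.
num_col <- function(df, col, allow_missing = FALSE) {
  x <- df[[col]]
  out <- suppressWarnings(as.numeric(x))
  empty <- x == ""
  bad <- is.na(out) & !empty
  if (any(bad)) {
    ln <- attr(df, "file_lines")[which(bad)[1]]
    stop(sprintf("%s: line %d: cannot parse '%s' field '%s' as a number",
                 attr(df, "path"), ln, col, x[which(bad)[1]]), call. = FALSE)
  }
  if (!allow_missing && any(empty)) {
    ln <- attr(df, "file_lines")[which(empty)[1]]
    stop(sprintf("%s: line %d: field '%s' is required", attr(df, "path"),
                 ln, col), call. = FALSE)
  }
  out
}

fmt_num <- function(x) {
  out <- ifelse(is.na(x), "", format(x, digits = 15, scientific = FALSE,
                                     trim = TRUE))
  out
}

#' Read an interbeat-interval file
#'
#' Expects comma-separated text with header columns `time_s` (seconds since
#' recording start, strictly increasing) and `ibi_ms` (positive interbeat
#' intervals in milliseconds). An optional `valid` column (0/1) carries
#' artifact marks; absent, all samples are valid.
#'
#' @param path Path to the file.
#' @param person_id Person identifier attached to the stream.
#' @return An [ibi_stream()].
#' @seealso [write_ibi()], [clean_ibis()]
#' @export
read_ibi <- function(path, person_id = "p1") {
  raw <- read_csv_strict(path, c("time_s", "ibi_ms"))
  time_s <- num_col(raw, "time_s")
  ibi_ms <- num_col(raw, "ibi_ms")
  valid <- NULL
  hdr <- readLines(path, n = 1L)
  if (grepl("(^|,)\\s*valid\\s*(,|$)", hdr)) {
    valid <- num_col(read_csv_strict(path, "valid"), "valid") != 0
  }
  ibi_stream(time_s, ibi_ms, person_id = person_id, valid = valid)
}

#' Write an interbeat-interval file
#' @param stream An [ibi_stream()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ibi <- function(stream, path) {
  stopifnot(inherits(stream, "ibi_stream"))
  lines <- c("time_s,ibi_ms,valid",
             sprintf("%s,%s,%d", fmt_num(stream$time_s),
                     fmt_num(stream$ibi_ms), as.integer(stream$valid)))
  writeLines(lines, path)
  invisible(path)
}

#' Read / write an epoch-series file
#'
#' Four columns: `start_s`, `rmssd_ms`, `accel_g`, `valid` (0/1). Missing
#' RMSSD or acceleration values are empty fields and force `valid = 0`.
#' `read_epochs(write_epochs(x))` reproduces `x` field for field.
#'
#' @param path File path.
#' @param person_id Person identifier.
#' @param epoch_length Epoch duration in seconds used to validate the start
#'   grid (default 30).
#' @return An [epoch_series()].
#' @export
read_epochs <- function(path, person_id = "p1", epoch_length = 30) {
  raw <- read_csv_strict(path, c("start_s", "rmssd_ms", "accel_g", "valid"))
  epoch_series(num_col(raw, "start_s"),
               num_col(raw, "rmssd_ms", allow_missing = TRUE),
               num_col(raw, "accel_g", allow_missing = TRUE),
               valid = num_col(raw, "valid") != 0,
               person_id = person_id, epoch_length = epoch_length)
}

#' @rdname read_epochs
#' @param series An [epoch_series()] to write.
#' @export
write_epochs <- function(series, path) {
  stopifnot(inherits(series, "epoch_series"))
  lines <- c("start_s,rmssd_ms,accel_g,valid",
             sprintf("%s,%s,%s,%d", fmt_num(series$start_s),
                     fmt_num(series$rmssd_ms), fmt_num(series$accel_g),
                     as.integer(series$valid)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a calibration phase annotation file
#'
#' Expects columns `label`, `start_s`, `end_s`. Labels must come from the
#' five-phase vocabulary ([CALIBRATION_PHASES]); windows are half-open
#' `[start_s, end_s)` and may not overlap. Phases are returned sorted by
#' start time.
#'
#' @param path File path.
#' @return A data frame of phases (`label`, `start_s`, `end_s`).
#' @export
read_calibration_annotation <- function(path) {
  raw <- read_csv_strict(path, c("label", "start_s", "end_s"))
  validate_phases(data.frame(label = raw$label,
                             start_s = num_col(raw, "start_s"),
                             end_s = num_col(raw, "end_s")))
}

#' @rdname read_calibration_annotation
#' @param phases Phase data frame to write.
#' @export
write_calibration_annotation <- function(phases, path) {
  phases <- validate_phases(phases)
  lines <- c("label,start_s,end_s",
             sprintf("%s,%s,%s", phases$label, fmt_num(phases$start_s),
                     fmt_num(phases$end_s)))
  writeLines(lines, path)
  invisible(path)
}

#' Read hourly self-report data
#'
#' Hourly ecological momentary assessment reports: for each prompt, the
#' number of worry and stress episodes experienced during the preceding hour,
#' plus optional affect ratings and episode duration/intensity columns. Hour
#' windows are half-open, 3600 s long and identified by their end time.
#'
#' Required columns: `hour_end_s`, `worry_count`, `stress_count`. Any further
#' numeric columns (e.g. `explicit_na`, `implicit_pa`, `worry_duration_min`)
#' are carried through as-is.
#'
#' @param path File path.
#' @param person_id Person identifier.
#' @return A data frame with attribute `person_id`, sorted by `hour_end_s`.
#' @export
read_hourly_reports <- function(path, person_id = "p1") {
  hdr <- trimws(strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1]])
  raw <- read_csv_strict(path, hdr)
  need <- c("hour_end_s", "worry_count", "stress_count")
  out <- data.frame(hour_end_s = num_col(raw, "hour_end_s"))
  for (col in c("worry_count", "stress_count")) {
    v <- num_col(raw, col)
    if (any(v < 0 | v != floor(v))) {
      stop(sprintf("%s: '%s' must be a non-negative integer count",
                   path, col), call. = FALSE)
    }
    out[[col]] <- as.integer(v)
  }
  for (col in setdiff(hdr, need)) {
    out[[col]] <- num_col(raw, col, allow_missing = TRUE)
  }
  out <- out[order(out$hour_end_s), , drop = FALSE]
  if (nrow(out) > 1 && any(diff(out$hour_end_s) < 3600 - 1e-9)) {
    stop(sprintf("%s: hour windows overlap (end times < 3600 s apart)", path),
         call. = FALSE)
  }
  rownames(out) <- NULL
  attr(out, "person_id") <- as.character(person_id)
  out
}

#' @rdname read_hourly_reports
#' @param reports Hourly report data frame to write.
#' @export
write_hourly_reports <- function(reports, path) {
  df <- as.data.frame(reports)
  cols <- names(df)
  body <- do.call(paste, c(lapply(df, fmt_num), sep = ","))
  writeLines(c(paste(cols, collapse = ","), body), path)
  invisible(path)
}

#' Write / read a person-model table
#'
#' One row per person: fitted intercept and slope of the inverse
#' movement-to-RMSSD model, the calibration SE, fit diagnostics, resting
#' RMSSD, exclusion status and the detector configuration.
#'
#' @param models A `person_model` or list of them.
#' @param path File path.
#' @return `write_person_models()` returns `path` invisibly;
#'   `read_person_models()` returns a list of `person_model` objects.
#' @export
write_person_models <- function(models, path) {
  if (inherits(models, "person_model")) models <- list(models)
  rows <- vapply(models, function(m) {
    sprintf("%s,%s,%s,%s,%s,%s,%s,%s,%s,%s,%s,%s",
            m$person_id, fmt_num(m$b0), fmt_num(m$b1), fmt_num(m$se),
            fmt_num(m$r2), fmt_num(m$b1_pvalue), fmt_num(m$resting_rmssd),
            m$status, fmt_num(m$k), fmt_num(m$min_run),
            fmt_num(m$accel_floor), m$error_quantity)
  }, character(1))
  writeLines(c(paste("person_id,b0,b1,se,r2,b1_pvalue,resting_rmssd,status,",
                     "k,min_run,accel_floor,error_quantity", sep = ""),
               rows), path)
  invisible(path)
}

#' @rdname write_person_models
#' @export
read_person_models <- function(path) {
  cols <- c("person_id", "b0", "b1", "se", "r2", "b1_pvalue",
            "resting_rmssd", "status", "k", "min_run", "accel_floor",
            "error_quantity")
  raw <- read_csv_strict(path, cols)
  lapply(seq_len(nrow(raw)), function(i) {
    row <- raw[i, , drop = FALSE]
    attr(row, "path") <- attr(raw, "path")
    attr(row, "file_lines") <- attr(raw, "file_lines")[i]
    structure(list(
      person_id = row$person_id,
      b0 = num_col(row, "b0", TRUE), b1 = num_col(row, "b1", TRUE),
      se = num_col(row, "se", TRUE), r2 = num_col(row, "r2", TRUE),
      b1_pvalue = num_col(row, "b1_pvalue", TRUE),
      resting_rmssd = num_col(row, "resting_rmssd", TRUE),
      status = row$status, k = num_col(row, "k"),
      min_run = as.integer(num_col(row, "min_run")),
      accel_floor = num_col(row, "accel_floor"),
      error_quantity = row$error_quantity), class = "person_model")
  })
}

#' Write detection outputs
#'
#' `write_episodes()` emits one row per detected episode (person, start
#' index, start time, length in epochs); `write_hourly_coding()` emits the
#' hourly table (person, hour end, 0/1 AddHRVr code, overlapping-episode
#' count, hourly mean RMSSD and acceleration, valid-epoch count).
#'
#' @param episodes An `episode_set` (see [detect_episodes()]).
#' @param hourly An `hourly_coding` data frame (see [code_hours()]).
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_episodes <- function(episodes, path) {
  stopifnot(inherits(episodes, "episode_set"))
  ep <- episodes$episodes
  lines <- c("person_id,start_index,start_s,length_epochs",
             if (nrow(ep)) sprintf("%s,%d,%s,%d", episodes$person_id,
                                   ep$start_index, fmt_num(ep$start_s),
                                   ep$length))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_episodes
#' @export
write_hourly_coding <- function(hourly, path) {
  df <- as.data.frame(hourly)
  pid <- attr(hourly, "person_id")
  lines <- c(
    "person_id,hour_end_s,add_hrvr,n_episodes,mean_rmssd,mean_accel,n_valid_epochs",
    if (nrow(df)) sprintf("%s,%s,%d,%d,%s,%s,%d", pid,
                          fmt_num(df$hour_end_s), df$add_hrvr, df$n_episodes,
                          fmt_num(df$mean_rmssd), fmt_num(df$mean_accel),
                          df$n_valid_epochs))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_episodes
#' @param person_id Person identifier for the rows read.
#' @export
read_hourly_coding <- function(path, person_id = NULL) {
  cols <- c("person_id", "hour_end_s", "add_hrvr", "n_episodes",
            "mean_rmssd", "mean_accel", "n_valid_epochs")
  raw <- read_csv_strict(path, cols)
  out <- data.frame(person_id = raw$person_id,
                    hour_end_s = num_col(raw, "hour_end_s"),
                    add_hrvr = as.integer(num_col(raw, "add_hrvr")),
                    n_episodes = as.integer(num_col(raw, "n_episodes")),
                    mean_rmssd = num_col(raw, "mean_rmssd", TRUE),
                    mean_accel = num_col(raw, "mean_accel", TRUE),
                    n_valid_epochs = as.integer(num_col(raw,
                                                        "n_valid_epochs")))
  if (!is.null(person_id)) out <- out[out$person_id %in% person_id, ]
  out
}
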