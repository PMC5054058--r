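#' Within/between-person decomposition of an hourly variable
#'
#' Person-mean centering: for each person the stable between-person component
#' is the mean of their hourly values, and the within-person component is
#' each hour's deviation from that mean. `between + within` reconstructs the
#' hourly value exactly, and within deviations sum to zero per person. The
#' output layout (one row per person-hour) is directly consumable by
#' mixed-model tools.
#'
#' @param hourly Data frame with columns `person_id`, `hour_end_s` and the
#'   hourly variable named by `value`.
#' @param value Name of the hourly column to decompose; default `"add_hrvr"`
#'   (the 0/1 hour code). Set to `"n_episodes"` to decompose episode counts
#'   instead.
#' @return The input with appended columns `<value>_between` and
#'   `<value>_within`. Persons with zero hours are skipped with a warning.
#' @export
decompose_within_between <- function(hourly, value = "add_hrvr") {
  hourly <- as.data.frame(hourly)
  if (!all(c("person_id", value) %in% names(hourly))) {
    stop(sprintf("decompose_within_between: need columns person_id and %s",
                 value), call. = FALSE)
  }
  v <- hourly[[value]]
  if (anyNA(v)) {
    stop("decompose_within_between: hourly values must be non-missing",
         call. = FALSE)
  }
  pm <- tapply(v, hourly$person_id, mean)
  between <- as.vector(pm[as.character(hourly$person_id)])
  hourly[[paste0(value, "_between")]] <- between
  hourly[[paste0(value, "_within")]] <- v - between
  hourly
}

#' Aggregate hourly tables into per-person summaries
#'
#' Joins the hourly detection codes with the hourly self-reports on
#' (`person_id`, `hour_end_s`) and totals them per person: hours with
#' AddHRVr, episode count, worry and stress episode totals, and means of any
#' affect columns present in the reports. Persons present in only one table
#' get missing values for the other table's summaries.
#'
#' @param hourly Hourly detection table (`person_id`, `hour_end_s`,
#'   `add_hrvr`, `n_episodes`, ...).
#' @param reports Optional hourly report table (`person_id`, `hour_end_s`,
#'   `worry_count`, `stress_count`, affect columns).
#' @return One row per person: `person_id`, `n_hours`, `total_addhrvr_hours`,
#'   `total_episodes`, `total_worry_episodes`, `total_stress_episodes`,
#'   `n_worry_hours`, `n_stress_hours`, and `mean_<affect>` columns.
#' @export
aggregate_persons <- function(hourly, reports = NULL) {
  hourly <- as.data.frame(hourly)
  need <- c("person_id", "hour_end_s", "add_hrvr")
  if (!all(need %in% names(hourly))) {
    stop("aggregate_persons: hourly table needs person_id, hour_end_s, add_hrvr",
         call. = FALSE)
  }
  persons <- unique(as.character(hourly$person_id))
  out <- data.frame(person_id = persons)
  by_p <- split(hourly, factor(hourly$person_id, levels = persons))
  out$n_hours <- vapply(by_p, nrow, integer(1))
  out$total_addhrvr_hours <- vapply(by_p, function(d) sum(d$add_hrvr),
                                    numeric(1))
  out$total_episodes <- if ("n_episodes" %in% names(hourly)) {
    vapply(by_p, function(d) sum(d$n_episodes), numeric(1))
  } else rep(NA_real_, length(persons))
  out$total_worry_episodes <- rep(NA_real_, length(persons))
  out$total_stress_episodes <- rep(NA_real_, length(persons))
  out$n_worry_hours <- rep(NA_real_, length(persons))
  out$n_stress_hours <- rep(NA_real_, length(persons))
  if (!is.null(reports)) {
    reports <- as.data.frame(reports)
    if (!all(c("person_id", "hour_end_s") %in% names(reports))) {
      stop("aggregate_persons: reports need person_id and hour_end_s",
           call. = FALSE)
    }
    extra <- setdiff(unique(as.character(reports$person_id)), persons)
    if (length(extra)) {
      stop(sprintf("aggregate_persons: report person id(s) absent from hourly table: %s",
                   paste(extra, collapse = ", ")), call. = FALSE)
    }
    rep_p <- split(reports, factor(reports$person_id, levels = persons))
    has <- vapply(rep_p, nrow, integer(1)) > 0
    grab <- function(f) {
      v <- rep(NA_real_, length(persons))
      v[has] <- vapply(rep_p[has], f, numeric(1))
      v
    }
    out$total_worry_episodes <- grab(function(d) sum(d$worry_count))
    out$total_stress_episodes <- grab(function(d) sum(d$stress_count))
    out$n_worry_hours <- grab(function(d) sum(d$worry_count > 0))
    out$n_stress_hours <- grab(function(d) sum(d$stress_count > 0))
    affect <- setdiff(names(reports),
                      c("person_id", "hour_end_s", "worry_count",
                        "stress_count"))
    for (col in affect) {
      out[[paste0("mean_", col)]] <-
        grab(function(d) mean(d[[col]], na.rm = TRUE))
    }
  }
  rownames(out) <- NULL
  out
}

#' Pearson correlation with a t-based p-value
#'
#' Sample Pearson correlation between two person-level vectors, with the
#' two-sided p-value from `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2`
#' degrees of freedom. Used for between-person associations on aggregated
#' data.
#'
#' @param x,y Numeric vectors, equal length `n >= 3`, finite, each with
#'   non-zero variance.
#' @return List with `r`, `p`, `df` (`n - 2`) and `n`.
#' @export
pearson_cor <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) {
    stop("pearson_cor: lengths differ", call. = FALSE)
  }
  if (length(x) < 3) stop("pearson_cor: need n >= 3", call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("pearson_cor: non-finite values", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("pearson_cor: undefined correlation (zero variance)", call. = FALSE)
  }
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  r <- max(-1, min(1, r))
  p <- if (abs(r) >= 1) 0 else {
    tval <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(tval), df = n - 2)
  }
  list(r = r, p = p, df = n - 2L, n = n)
}

#' Summarise an hourly study table
#'
#' Study-level descriptives over a multi-person hourly table: total
#' person-hours assessed, the percentage of hours with AddHRVr (and with
#' worry / stress episodes when report columns are present), and the mean
#' number of flagged hours per participant.
#'
#' @param hourly Hourly table with `person_id` and `add_hrvr`; optionally
#'   `worry_count` and `stress_count` (joined reports).
#' @return List with `n_hours`, `n_persons`, `n_addhrvr_hours`,
#'   `pct_addhrvr_hours`, `mean_addhrvr_hours_per_person`, and (when report
#'   columns are present) `n_worry_hours`, `pct_worry_hours`,
#'   `n_stress_hours`, `pct_stress_hours`. Percentages are on the 0--100
#'   scale.
#' @export
summarise_hours <- function(hourly) {
  hourly <- as.data.frame(hourly)
  stopifnot(all(c("person_id", "add_hrvr") %in% names(hourly)))
  n <- nrow(hourly)
  persons <- unique(hourly$person_id)
  flagged <- sum(hourly$add_hrvr > 0)
  out <- list(n_hours = n, n_persons = length(persons),
              n_addhrvr_hours = flagged,
              pct_addhrvr_hours = 100 * flagged / n,
              mean_addhrvr_hours_per_person = flagged / length(persons))
  if ("worry_count" %in% names(hourly)) {
    nw <- sum(hourly$worry_count > 0, na.rm = TRUE)
    out$n_worry_hours <- nw
    out$pct_worry_hours <- 100 * nw / n
  }
  if ("stress_count" %in% names(hourly)) {
    ns <- sum(hourly$stress_count > 0, na.rm = TRUE)
    out$n_stress_hours <- ns
    out$pct_stress_hours <- 100 * ns / n
  }
  out
}

#' Join hourly detection codes with hourly reports
#'
#' Inner-joins on (`person_id`, `hour_end_s`). Rows present in only one
#' table are dropped; a mismatch in person ids (a report person with no
#' detection rows at all) is an error.
#'
#' @param hourly Hourly detection table.
#' @param reports Hourly report table.
#' @return Merged data frame.
#' @export
join_hourly <- function(hourly, reports) {
  hourly <- as.data.frame(hourly); reports <- as.data.frame(reports)
  extra <- setdiff(unique(as.character(reports$person_id)),
                   unique(as.character(hourly$person_id)))
  if (length(extra)) {
    stop(sprintf("join_hourly: report person id(s) with no detection rows: %s",
                 paste(extra, collapse = ", ")), call. = FALSE)
  }
  out <- merge(hourly, reports, by = c("person_id", "hour_end_s"),
               sort = FALSE)
  out <- out[order(out$person_id, out$hour_end_s), , drop = FALSE]
  rownames(out) <- NULL
  out
}
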