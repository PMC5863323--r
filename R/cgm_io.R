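# CSV import/export for CGM traces and MAGE result records.

.parse_times <- function(x, time_format = NULL, tz = "UTC",
                         numeric_time_unit = c("sec", "min")) {
  numeric_time_unit <- match.arg(numeric_time_unit)
  if (is.numeric(x)) {
    t <- as.numeric(x)
    if (numeric_time_unit == "min") t <- t * 60
    return(list(times = t, start_time = NULL, bad = which(is.na(t))))
  }
  x <- as.character(x)
  # numeric columns read as character (e.g. quoted CSV)
  suppressWarnings(tn <- as.numeric(x))
  if (!anyNA(tn)) {
    if (numeric_time_unit == "min") tn <- tn * 60
    return(list(times = tn, start_time = NULL, bad = integer(0)))
  }
  fmts <- if (!is.null(time_format)) time_format else
    c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS", "%Y-%m-%d %H:%M",
      "%Y/%m/%d %H:%M:%OS", "%Y/%m/%d %H:%M")
  best <- rep(as.POSIXct(NA), length(x))
  for (f in fmts) {
    p <- as.POSIXct(x, format = f, tz = tz)
    fill <- is.na(best) & !is.na(p)
    best[fill] <- p[fill]
    if (!anyNA(best)) break
  }
  list(times = best, start_time = NULL, bad = which(is.na(best) & !is.na(x)))
}

#' Read a CGM trace from a delimited text file
#'
#' Reads a CSV (or other delimited) export with one timestamp column and one
#' glucose column, validates it and returns a [glucose_trace()] in mmol/L.
#' Rows are sorted by time; duplicate timestamps are an error (averaging them
#' silently would change SDBG and hence the MAGE threshold).
#'
#' @param path path to the file.
#' @param time_col,glucose_col column names (defaults `"time"`, `"glucose"`).
#' @param unit unit of the glucose column: `"mmol_L"` or `"mg_dL"`
#'   (converted with the fixed divisor 18.016).
#' @param sep field delimiter.
#' @param time_format optional `strptime`-style format(s) for character
#'   timestamps; by default common ISO 8601 layouts are tried. Numeric time
#'   columns are taken as seconds since trace start (or minutes with
#'   `numeric_time_unit = "min"`).
#' @param numeric_time_unit unit of a numeric time column.
#' @param trace_id label for the trace; defaults to the file name.
#' @param tz time zone for parsing calendar timestamps.
#' @return a [glucose_trace()].
#' @export
read_cgm_csv <- function(path, time_col = "time", glucose_col = "glucose",
                         unit = c("mmol_L", "mg_dL"), sep = ",",
                         time_format = NULL, numeric_time_unit = "sec",
                         trace_id = NULL, tz = "UTC") {
  unit <- match.arg(unit)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, sep = sep, stringsAsFactors = FALSE,
                 check.names = FALSE)
  for (col in c(time_col, glucose_col)) {
    if (!col %in% names(df)) {
      stop(sprintf("column '%s' not found in %s (columns: %s)",
                   col, path, paste(names(df), collapse = ", ")),
           call. = FALSE)
    }
  }
  if (nrow(df) < 2L) {
    stop("trace in ", path, " has fewer than 2 rows", call. = FALSE)
  }
  suppressWarnings(g <- as.numeric(df[[glucose_col]]))
  bad_g <- which(is.na(g) & !is.na(df[[glucose_col]]))
  if (length(bad_g)) {
    stop(sprintf("non-numeric glucose value at data row %s of %s",
                 paste(bad_g, collapse = ", "), path), call. = FALSE)
  }
  pt <- .parse_times(df[[time_col]], time_format = time_format, tz = tz,
                     numeric_time_unit = numeric_time_unit)
  if (length(pt$bad)) {
    stop(sprintf("unparseable timestamp at data row %s of %s",
                 paste(pt$bad, collapse = ", "), path), call. = FALSE)
  }
  t <- pt$times
  ord <- order(t)
  t <- t[ord]; g <- g[ord]
  if (anyDuplicated(t)) {
    stop("duplicate timestamps in ", path,
         " (remove or disambiguate; they are not averaged)", call. = FALSE)
  }
  if (is.null(trace_id)) {
    trace_id <- sub("\\.[^.]*$", "", basename(path))
  }
  glucose_trace(t, g, unit = unit, trace_id = trace_id)
}

#' Split a trace into consecutive 24-hour windows
#'
#' Cuts the trace into non-overlapping windows of `window_hours` starting at
#' the first observation. A window counts as complete when its observations
#' span at least `min_span_hours` and contain no sampling gap longer than
#' `max_gap_hours`; this tolerates minor sensor dropouts in a nominal 24-h
#' recording. Incomplete windows are dropped from the returned list and
#' reported in the `"incomplete_windows"` attribute.
#'
#' @param trace a [glucose_trace()].
#' @param window_hours window length (default 24).
#' @param min_span_hours minimum observed span for a complete window.
#' @param max_gap_hours maximum tolerated gap between consecutive samples.
#' @return list of complete-window [glucose_trace()]s in time order, with
#'   attributes `n_windows` (windows containing any data) and
#'   `incomplete_windows` (indices of the flagged ones).
#' @export
segment_24h <- function(trace, window_hours = 24, min_span_hours = 20,
                        max_gap_hours = 2) {
  stopifnot(inherits(trace, "glucose_trace"))
  w <- window_hours * 3600
  t0 <- trace$times[1L]
  rel <- trace$times - t0
  win <- floor(rel / w)
  idx_by_win <- split(seq_along(rel), win)
  out <- list()
  incomplete <- integer(0)
  for (wi in seq_along(idx_by_win)) {
    idx <- idx_by_win[[wi]]
    wnum <- as.integer(names(idx_by_win)[wi]) + 1L
    ts <- trace$times[idx]
    ok <- length(idx) >= 2L &&
      (max(ts) - min(ts)) >= min_span_hours * 3600 &&
      max(diff(ts)) <= max_gap_hours * 3600
    if (ok) {
      out[[length(out) + 1L]] <- glucose_trace(
        ts - min(ts), trace$values[idx], trace_id =
          sprintf("%s_day%d", trace$trace_id, wnum))
    } else {
      incomplete <- c(incomplete, wnum)
    }
  }
  structure(out, n_windows = length(idx_by_win),
            incomplete_windows = incomplete)
}

.record_fields <- c("trace_id", "sdbg", "mage_plus", "mage_minus", "mage",
                    "mage_a", "direction", "n_excursions",
                    "selected_times", "selected_values")

.record_to_row <- function(r) {
  data.frame(
    trace_id = r$trace_id,
    sdbg = r$sdbg,
    mage_plus = if (is.null(r$mage_plus)) NA_real_ else r$mage_plus,
    mage_minus = if (is.null(r$mage_minus)) NA_real_ else r$mage_minus,
    mage = r$mage,
    mage_a = if (is.null(r$mage_a)) NA_real_ else r$mage_a,
    direction = r$direction,
    n_excursions = r$n_excursions,
    selected_times = paste(format(r$selected_times, digits = 17,
                                  trim = TRUE, scientific = FALSE),
                           collapse = ";"),
    selected_values = paste(format(r$selected_values, digits = 17,
                                   trim = TRUE, scientific = FALSE),
                            collapse = ";"),
    stringsAsFactors = FALSE
  )
}

#' Write MAGE result records to CSV or JSON
#'
#' One row (CSV) or object (JSON) per trace. Undefined statistics (e.g.
#' MAGE- on a trace whose only countable excursions rise) are written as
#' empty cells / JSON `null`, never as 0, so that batch averages are not
#' biased.
#'
#' @param records a [mage_result] or list of them.
#' @param path output file path.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @seealso [read_results()]
#' @export
write_results <- function(records, path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (inherits(records, "mage_result")) records <- list(records)
  if (!length(records)) stop("`records` must be non-empty", call. = FALSE)
  if (format == "csv") {
    df <- do.call(rbind, lapply(records, .record_to_row))
    write.csv(df, path, row.names = FALSE, na = "")
  } else {
    objs <- lapply(records, function(r) {
      r[c("trace_id", "sdbg", "mage_plus", "mage_minus", "mage", "mage_a",
          "direction", "n_excursions", "selected_times", "selected_values")]
    })
    jsonlite::write_json(objs, path, auto_unbox = TRUE, digits = NA,
                         null = "null", na = "null")
  }
  invisible(path)
}

#' Read MAGE result records written by [write_results()]
#'
#' @param path file written by [write_results()].
#' @param format `"csv"` or `"json"`.
#' @return list of [mage_result] objects.
#' @export
read_results <- function(path, format = c("csv", "json")) {
  format <- match.arg(format)
  split_num <- function(s) {
    if (is.null(s) || is.na(s) || !nzchar(s)) return(numeric(0))
    as.numeric(strsplit(s, ";", fixed = TRUE)[[1L]])
  }
  if (format == "csv") {
    df <- read.csv(path, stringsAsFactors = FALSE)
    recs <- lapply(seq_len(nrow(df)), function(i) {
      row <- df[i, ]
      new_mage_result(
        trace_id = row$trace_id, sdbg = row$sdbg,
        mage_plus = row$mage_plus, mage_minus = row$mage_minus,
        mage = row$mage, mage_a = row$mage_a,
        direction = row$direction, n_excursions = row$n_excursions,
        selected_times = split_num(as.character(row$selected_times)),
        selected_values = split_num(as.character(row$selected_values)))
    })
  } else {
    objs <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    recs <- lapply(objs, function(o) {
      num_or_na <- function(x) if (is.null(x)) NA_real_ else as.numeric(x)
      new_mage_result(
        trace_id = o$trace_id, sdbg = num_or_na(o$sdbg),
        mage_plus = num_or_na(o$mage_plus),
        mage_minus = num_or_na(o$mage_minus),
        mage = num_or_na(o$mage), mage_a = num_or_na(o$mage_a),
        direction = o$direction, n_excursions = as.integer(o$n_excursions),
        selected_times = as.numeric(unlist(o$selected_times)),
        selected_values = as.numeric(unlist(o$selected_values)))
    })
  }
  recs
}
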