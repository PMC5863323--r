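# Glucose trace container. Values are stored in mmol/L regardless of the
# input unit; times are seconds since the first observation.

# Molar mass of glucose is 180.16 g/mol, so 1 mmol/L = 18.016 mg/dL.
MGDL_PER_MMOL <- 18.016

#' Convert glucose concentrations between mg/dL and mmol/L
#'
#' Uses the fixed divisor 18.016 (molar mass of glucose 180.16 g/mol),
#' the same constant everywhere in the package.
#'
#' @param x numeric vector of concentrations.
#' @return numeric vector in the other unit.
#' @examples
#' mgdl_to_mmol(90)
#' mmol_to_mgdl(mgdl_to_mmol(90))
#' @export
mgdl_to_mmol <- function(x) x / MGDL_PER_MMOL

#' @rdname mgdl_to_mmol
#' @export
mmol_to_mgdl <- function(x) x * MGDL_PER_MMOL

#' Construct a glucose trace
#'
#' A `glucose_trace` holds one CGM recording: strictly increasing times (in
#' seconds since the first sample) and positive, finite glucose values stored
#' in mmol/L. Values supplied in mg/dL are converted on construction.
#'
#' @param times numeric vector of times. Either seconds since trace start or
#'   a `POSIXct` vector; `POSIXct` input is rebased to seconds since the
#'   first observation and the origin kept as `start_time`.
#' @param values numeric vector of glucose concentrations, same length as
#'   `times`.
#' @param unit unit of `values`: `"mmol_L"` (default) or `"mg_dL"`.
#' @param trace_id label carried through to results.
#' @param start_time optional `POSIXct` origin of the trace.
#' @return an object of class `glucose_trace` with fields `times`, `values`
#'   (mmol/L), `unit_of_origin`, `trace_id`, `start_time`.
#' @examples
#' glucose_trace(c(0, 300, 600), c(5.0, 6.2, 5.4))
#' @export
glucose_trace <- function(times, values, unit = c("mmol_L", "mg_dL"),
                          trace_id = "trace", start_time = NULL) {
  unit <- match.arg(unit)
  if (inherits(times, "POSIXct")) {
    if (is.null(start_time)) start_time <- min(times)
    times <- as.numeric(times) - as.numeric(start_time)
  }
  times <- as.numeric(times)
  values <- as.numeric(values)
  if (length(times) != length(values)) {
    stop("`times` and `values` must have the same length", call. = FALSE)
  }
  if (length(times) < 2L) {
    stop("a glucose trace needs at least 2 observations", call. = FALSE)
  }
  if (anyNA(times) || any(!is.finite(times))) {
    stop("non-finite timestamps in trace", call. = FALSE)
  }
  if (any(diff(times) <= 0)) {
    stop("timestamps must be strictly increasing (duplicates are an error)",
         call. = FALSE)
  }
  if (unit == "mg_dL") values <- mgdl_to_mmol(values)
  if (anyNA(values) || any(!is.finite(values)) || any(values <= 0)) {
    stop("glucose values must be positive and finite", call. = FALSE)
  }
  structure(
    list(times = times, values = values, unit_of_origin = unit,
         trace_id = as.character(trace_id), start_time = start_time),
    class = "glucose_trace"
  )
}

#' @export
print.glucose_trace <- function(x, ...) {
  span_h <- (max(x$times) - min(x$times)) / 3600
  cat(sprintf(
    "<glucose_trace '%s'> %d samples over %.1f h, %.2f-%.2f mmol/L\n",
    x$trace_id, length(x$values), span_h, min(x$values), max(x$values)))
  invisible(x)
}

#' @export
length.glucose_trace <- function(x) length(x$values)

#' @export
as.data.frame.glucose_trace <- function(x, ...) {
  data.frame(time = x$times, glucose = x$values)
}
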