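#' Construct an electropherogram object
#'
#' A capillary-electrophoresis trace: ordered (axis value, signal) points on
#' either a raw migration-time axis or a calibrated size axis in nt.
#'
#' @param trace Data frame whose first two columns are the axis value and
#'   the fluorescence signal (or columns named `size_nt`/`migration_time`
#'   and `signal`).
#' @param axis_kind `"size_nt"` or `"migration_time"`.
#' @param sample_name Sample label.
#' @param markers Optional marker table (columns `size_nt`, `axis_value`).
#' @return A tibble of class `electropherogram` with columns named after
#'   the axis kind plus `signal`.
#' @export
electropherogram <- function(trace, axis_kind = c("size_nt", "migration_time"),
                             sample_name = "sample", markers = NULL) {
  axis_kind <- match.arg(axis_kind)
  trace <- as_tibble(trace)
  if (!all(c(axis_kind, "signal") %in% names(trace))) {
    names(trace)[1:2] <- c(axis_kind, "signal")
  }
  trace <- trace[, c(axis_kind, "signal")]
  ax <- trace[[axis_kind]]
  if (is.unsorted(ax, strictly = TRUE)) {
    abort("axis values must be strictly increasing",
          class = "mprtseq_input_error")
  }
  attr(trace, "axis_kind") <- axis_kind
  attr(trace, "sample_name") <- sample_name
  attr(trace, "markers") <- markers
  class(trace) <- c("electropherogram", class(trace))
  trace
}

#' Read / write an electropherogram trace CSV
#'
#' Two columns: axis value (migration time or size in nt) and signal.
#'
#' @param path CSV path.
#' @param axis_kind Axis interpretation of the first column.
#' @return `read_trace()` returns an [electropherogram()].
#' @export
read_trace <- function(path, axis_kind = "migration_time") {
  tb <- readr::read_csv(path, col_types = readr::cols())
  electropherogram(tb, axis_kind = axis_kind,
                   sample_name = sub("\\.csv$", "", basename(path)))
}

#' @param eph An [electropherogram()].
#' @rdname read_trace
#' @export
write_trace <- function(eph, path) {
  readr::write_csv(as_tibble(eph), path)
  invisible(path)
}

#' Calibrate a migration-time trace to a size axis
#'
#' Electrophoretic mobility is approximately linear in log(length), so
#' size markers of known length are interpolated piecewise-linearly in
#' log(size) against axis value; queries beyond the marker range are
#' linearly extrapolated on the same scale.
#'
#' @param eph An [electropherogram()] on a migration-time axis.
#' @param markers Data frame with columns `size_nt` and `axis_value`
#'   (>= 2 rows, jointly monotone).
#' @return An [electropherogram()] on a strictly increasing `size_nt` axis.
#' @export
calibrate_sizes <- function(eph, markers) {
  markers <- as_tibble(markers)
  stopifnot(all(c("size_nt", "axis_value") %in% names(markers)))
  if (nrow(markers) < 2) {
    abort("need at least two size markers", class = "mprtseq_calibration_error")
  }
  markers <- markers |> arrange(.data$axis_value)
  if (is.unsorted(markers$size_nt, strictly = TRUE)) {
    abort("markers must be jointly monotone in axis value and size",
          class = "mprtseq_calibration_error")
  }
  t <- as_tibble(eph)[[1]]
  logsize <- interp_extrap(markers$axis_value, log(markers$size_nt), t)
  out <- tibble(size_nt = exp(logsize), signal = as_tibble(eph)$signal)
  electropherogram(out, axis_kind = "size_nt",
                   sample_name = attr(eph, "sample_name") %||% "sample",
                   markers = markers)
}

# piecewise-linear interpolation with linear extrapolation at the ends
interp_extrap <- function(x, y, xout) {
  res <- approx(x, y, xout = xout, rule = 1)$y
  lo <- xout < x[1]
  hi <- xout > x[length(x)]
  if (any(lo)) {
    s <- (y[2] - y[1]) / (x[2] - x[1])
    res[lo] <- y[1] + s * (xout[lo] - x[1])
  }
  if (any(hi)) {
    n <- length(x)
    s <- (y[n] - y[n - 1]) / (x[n] - x[n - 1])
    res[hi] <- y[n] + s * (xout[hi] - x[n])
  }
  res
}

#' Rolling-minimum baseline correction
#'
#' Subtracts a rolling minimum of the signal (window in points) and clamps
#' at zero; a simple, openly specified stand-in for instrument baseline
#' removal.
#'
#' @param eph An [electropherogram()].
#' @param window Rolling window width in trace points (odd; default 51).
#' @return The corrected electropherogram; the window used is recorded in
#'   the `baseline_window` attribute.
#' @export
baseline_correct <- function(eph, window = 51) {
  sig <- as_tibble(eph)$signal
  if (length(sig) > window) {
    base <- zoo::rollapply(sig, window, min, fill = NA, partial = TRUE)
  } else {
    base <- rep(min(sig), length(sig))
  }
  out <- as_tibble(eph)
  out$signal <- pmax(0, sig - base)
  out2 <- electropherogram(out, axis_kind = attr(eph, "axis_kind"),
                           sample_name = attr(eph, "sample_name"),
                           markers = attr(eph, "markers"))
  attr(out2, "baseline_window") <- window
  out2
}

#' Integrity percentage and average fragment size
#'
#' Integrity is the percentage of trapezoidal trace area inside the
#' main-peak size window; average size is the area-weighted mean size over
#' the evaluated trace. Signal below `min_size` nt (e.g. the 20-nt
#' alignment-marker peak) is excluded from both numerator and denominator.
#'
#' @param eph An [electropherogram()] on a size axis (see
#'   [calibrate_sizes()]), baseline-corrected.
#' @param cutoff_lo,cutoff_hi Main-peak window bounds in nt (defaults
#'   2100-3300, the main-peak cutoff used for a ~2.9-knt construct).
#' @param min_size Sizes below this are ignored entirely (default 100 nt).
#' @return An object of class `integrity_result`: list with
#'   `integrity_percent`, `average_size_nt`, `window`, `total_area`,
#'   `window_area`, `min_size`. Has [glance()] and [tidy()] methods.
#' @export
integrity_percent <- function(eph, cutoff_lo = 2100, cutoff_hi = 3300,
                              min_size = 100) {
  stopifnot(cutoff_lo < cutoff_hi)
  if ((attr(eph, "axis_kind") %||% "size_nt") != "size_nt") {
    abort("trace must be on a size axis; run calibrate_sizes() first",
          class = "mprtseq_input_error")
  }
  tb <- as_tibble(eph)
  tb <- tb[tb$size_nt >= min_size, , drop = FALSE]
  if (nrow(tb) < 2 || sum(tb$signal) <= 0) {
    abort("trace has no signal above min_size", class = "mprtseq_input_error")
  }
  total <- pracma::trapz(tb$size_nt, tb$signal)
  if (total <= 0) abort("zero total trace area", class = "mprtseq_input_error")
  inw <- tb$size_nt >= cutoff_lo & tb$size_nt <= cutoff_hi
  win_area <- if (sum(inw) >= 2) {
    pracma::trapz(tb$size_nt[inw], tb$signal[inw])
  } else 0
  avg <- pracma::trapz(tb$size_nt, tb$signal * tb$size_nt) / total
  res <- list(integrity_percent = 100 * win_area / total,
              average_size_nt = avg,
              window = c(cutoff_lo, cutoff_hi),
              total_area = total,
              window_area = win_area,
              min_size = min_size,
              sample_name = attr(eph, "sample_name"))
  class(res) <- "integrity_result"
  res
}

#' @export
print.integrity_result <- function(x, ...) {
  cat(sprintf("<integrity_result> %s: %.1f%% in [%g, %g] nt; average size %.0f nt\n",
              x$sample_name %||% "sample", x$integrity_percent,
              x$window[1], x$window[2], x$average_size_nt))
  invisible(x)
}

#' @method glance integrity_result
#' @export
glance.integrity_result <- function(x, ...) {
  tibble(sample = x$sample_name %||% "sample",
         integrity_percent = x$integrity_percent,
         average_size_nt = x$average_size_nt,
         window_lo = x$window[1], window_hi = x$window[2],
         total_area = x$total_area, window_area = x$window_area)
}

#' @method tidy integrity_result
#' @export
tidy.integrity_result <- function(x, ...) glance.integrity_result(x, ...)

#' Write an integrity result as JSON
#'
#' @param result An [integrity_percent()] result.
#' @param path Output path.
#' @export
write_integrity_json <- function(result, path) {
  jsonlite::write_json(unclass(result), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
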