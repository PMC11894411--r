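#' Construct a gaze stream
#'
#' A gaze stream is a tibble of time-stamped screen-gaze samples with a
#' validity flag, carrying the screen geometry and nominal sampling rate as
#' attributes. Columns: `t_s` (seconds, strictly increasing), `x_px`,
#' `y_px` (screen pixels, origin top-left, x rightward, y downward), and
#' `valid` (logical; invalid samples carry no usable position).
#'
#' @param samples A data frame with columns `t_s`, `x_px`, `y_px`, `valid`.
#' @param geometry A [screen_geometry()].
#' @param rate_hz Nominal sampling rate in Hz (default 100, the tracker's
#'   gaze data rate).
#' @return A `gaze_stream` tibble.
#' @export
gaze_stream <- function(samples, geometry = screen_geometry(), rate_hz = 100) {
  check_geometry(geometry)
  check_number(rate_hz, "rate_hz", positive = TRUE)
  check_columns(samples, c("t_s", "x_px", "y_px", "valid"), "gaze samples")
  check_monotone_time(samples$t_s, "gaze stream")
  out <- tibble::as_tibble(samples[, c("t_s", "x_px", "y_px", "valid")])
  out$valid <- as.logical(out$valid)
  structure(out,
            geometry = geometry, rate_hz = rate_hz,
            class = c("gaze_stream", class(tibble::tibble())))
}

#' @export
print.gaze_stream <- function(x, ...) {
  cat(sprintf("<gaze_stream> %d samples @ %g Hz, %.1f%% valid\n",
              nrow(x), attr(x, "rate_hz"), 100 * mean(x$valid)))
  NextMethod()
}

#' Geometry and rate accessors for stream tibbles
#'
#' @param stream A `gaze_stream` (or any stream tibble carrying the
#'   attribute).
#' @return The attached [screen_geometry()] / sampling rate.
#' @export
stream_geometry <- function(stream) {
  g <- attr(stream, "geometry")
  if (is.null(g)) gc_abort("Stream carries no screen geometry.",
                           "gc_invalid_geometry")
  g
}

#' @rdname stream_geometry
#' @export
stream_rate <- function(stream) {
  r <- attr(stream, "rate_hz")
  if (is.null(r)) gc_abort("Stream carries no sampling rate.",
                           "gc_invalid_parameter")
  r
}

#' Moving-window average smoothing of a gaze stream
#'
#' Replaces each valid sample position by the mean of the valid samples in
#' a centred window of `window` samples. The window shrinks at the stream
#' boundaries (no padding); invalid samples are excluded from the mean and
#' a window containing no valid samples yields an invalid output sample.
#' Timestamps and stream length are never altered.
#'
#' @param stream A [gaze_stream()].
#' @param window Odd window length in samples (default 5).
#' @return A smoothed `gaze_stream` of identical length and timestamps.
#' @export
smooth_gaze <- function(stream, window = 5) {
  if (!is.numeric(window) || length(window) != 1 || window < 1 ||
      window != round(window) || window %% 2 == 0) {
    gc_abort("`window` must be an odd positive integer.",
             "gc_invalid_parameter")
  }
  n <- nrow(stream)
  if (window == 1 || n == 0) return(stream)
  h <- (window - 1) / 2
  v <- stream$valid & is.finite(stream$x_px) & is.finite(stream$y_px)
  xs <- ifelse(v, stream$x_px, 0)
  ys <- ifelse(v, stream$y_px, 0)
  cx <- c(0, cumsum(xs)); cy <- c(0, cumsum(ys)); cn <- c(0, cumsum(v))
  lo <- pmax(seq_len(n) - h, 1)
  hi <- pmin(seq_len(n) + h, n)
  nv <- cn[hi + 1] - cn[lo]
  mx <- (cx[hi + 1] - cx[lo]) / nv
  my <- (cy[hi + 1] - cy[lo]) / nv
  out <- stream
  keep <- v & nv > 0
  out$x_px[keep] <- mx[keep]
  out$y_px[keep] <- my[keep]
  dead <- v & nv == 0  # cannot occur with shrink-to-valid windows, kept for safety
  out$valid[dead] <- FALSE
  out
}
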