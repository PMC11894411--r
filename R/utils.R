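# Internal helpers shared across modules.

gc_abort <- function(message, class) {
  rlang::abort(message, class = c(class, "gazechar_error"))
}

check_number <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    gc_abort(sprintf("`%s` must be a single finite number.", name),
             "gc_invalid_parameter")
  }
  if (positive && x <= 0) {
    gc_abort(sprintf("`%s` must be strictly positive.", name),
             "gc_invalid_parameter")
  }
  if (nonneg && x < 0) {
    gc_abort(sprintf("`%s` must be non-negative.", name),
             "gc_invalid_parameter")
  }
  invisible(x)
}

check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    gc_abort(sprintf("%s is missing required column(s): %s.",
                     what, paste0("\"", missing, "\"", collapse = ", ")),
             "gc_schema_error")
  }
  invisible(df)
}

check_monotone_time <- function(t, what) {
  if (anyNA(t) || any(!is.finite(t))) {
    gc_abort(sprintf("%s has missing or non-finite timestamps.", what),
             "gc_schema_error")
  }
  if (length(t) > 1 && any(diff(t) <= 0)) {
    gc_abort(sprintf("%s timestamps must be strictly increasing.", what),
             c("gc_nonmonotone_time", "gc_schema_error"))
  }
  invisible(t)
}

# Contiguous runs of a logical vector; returns tibble(start, end) of TRUE runs.
true_runs <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  tibble::tibble(start = starts[r$values], end = ends[r$values])
}

#' Left-aligned rolling windows over a time span
#'
#' Generates the 10 s / 5 s-step windows used by all rolling workload
#' metrics. A window is emitted only when it fits entirely inside
#' `[t0, t1]`.
#'
#' @param t0,t1 Span start and end, seconds.
#' @param win_s Window length in seconds (default 10).
#' @param step_s Step between window starts in seconds (default 5).
#' @return A tibble with columns `t_start`, `t_end`, `t_center`.
#' @export
rolling_windows <- function(t0, t1, win_s = 10, step_s = 5) {
  check_number(win_s, "win_s", positive = TRUE)
  check_number(step_s, "step_s", positive = TRUE)
  if (t1 - t0 < win_s) {
    return(tibble::tibble(t_start = numeric(), t_end = numeric(),
                          t_center = numeric()))
  }
  starts <- seq(t0, t1 - win_s, by = step_s)
  tibble::tibble(t_start = starts, t_end = starts + win_s,
                 t_center = starts + win_s / 2)
}
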