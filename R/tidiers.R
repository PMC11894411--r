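# broom-style tidiers for fitted/analysis objects.

#' @export
tidy.success_curve_fit <- function(x, ...) {
  tibble::tibble(term = c("a", "b", "c"),
                 estimate = c(x$a, x$b, x$c))
}

#' @export
glance.success_curve_fit <- function(x, ...) {
  tibble::tibble(residual_norm = x$residual_norm,
                 plateau_onset_dva = x$plateau_onset_dva,
                 n = nrow(x$data))
}

#' @export
tidy.bland_altman <- function(x, ...) {
  x$points
}

#' @export
glance.bland_altman <- function(x, ...) {
  tibble::tibble(bias = x$bias, loa_low = x$loa_low, loa_high = x$loa_high,
                 frac_within = x$frac_within, n = x$n)
}

#' @export
tidy.dtw_result <- function(x, ...) {
  x$path
}

#' @export
glance.dtw_result <- function(x, ...) {
  tibble::tibble(cumulative_distance = x$cumulative_distance,
                 similarity = x$similarity,
                 path_length = nrow(x$path),
                 band_frac = x$band_frac,
                 band_halfwidth = x$band_halfwidth)
}

#' @export
glance.focus_result <- function(x, ...) {
  tibble::tibble(n_targets = nrow(x),
                 n_success = sum(x$success),
                 success_rate = mean(x$success),
                 mean_completion_s = mean(x$completion_s[x$success]))
}
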