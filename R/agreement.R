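# Statistical machinery for comparing workload metrics: ICC(3,1)
# consistency, Bland-Altman limits of agreement, Sakoe-Chiba-banded DTW
# with a normalized similarity, and the Mann-Whitney U test.

#' Intraclass correlation, single-rater two-way fixed effects (ICC(3,1))
#'
#' Consistency form: with subjects as rows (here: tasks) and raters as
#' columns (here: workload metrics),
#' `ICC = (MSR - MSE) / (MSR + (k - 1) * MSE)` where `MSR` is the
#' between-subject mean square, `MSE` the residual mean square of the
#' two-way decomposition, and `k` the number of raters. Bounded in
#' `[-1, 1]` and invariant to rater-specific additive offsets.
#'
#' @param x A numeric subjects x raters matrix with no missing cells
#'   (>= 2 subjects, >= 2 raters), or a tidy data frame with columns
#'   `subject`, `rater`, `value`.
#' @return A one-row tibble: `icc`, `msr`, `msc`, `mse`, `n_subjects`,
#'   `k_raters`.
#' @export
icc_single_fixed <- function(x) {
  if (is.data.frame(x) && !is.matrix(x)) {
    check_columns(x, c("subject", "rater", "value"), "`x`")
    wide <- tidyr::pivot_wider(x[, c("subject", "rater", "value")],
                               names_from = "rater", values_from = "value")
    x <- as.matrix(wide[, -1])
  }
  x <- as.matrix(x)
  n <- nrow(x); k <- ncol(x)
  if (n < 2 || k < 2 || anyNA(x)) {
    gc_abort("Rating matrix needs >= 2 subjects, >= 2 raters, no missing cells.",
             "gc_degenerate_input")
  }
  grand <- mean(x)
  sst <- sum((x - grand)^2)
  if (sst == 0) {
    gc_abort("Zero total variance in the rating matrix.",
             "gc_degenerate_input")
  }
  ssr <- k * sum((rowMeans(x) - grand)^2)
  ssc <- n * sum((colMeans(x) - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  tibble::tibble(icc = (msr - mse) / (msr + (k - 1) * mse),
                 msr = msr, msc = msc, mse = mse,
                 n_subjects = n, k_raters = k)
}

#' Bland-Altman agreement analysis
#'
#' For paired measurements `q` (query) and `r` (reference): bias is the
#' mean difference, the limits of agreement are
#' `bias +/- loa_mult * sd(d)` (sample SD), and `frac_within` is the
#' proportion of differences inside the limits (inclusive). With
#' `loa_mult = 1.96` the limits are the 95% LoA, the range expected to
#' contain ~95% of Gaussian differences.
#'
#' @param q,r Equal-length numeric vectors (n >= 3).
#' @param loa_mult SD multiplier for the limits (default 1.96).
#' @return A `bland_altman` object: list with `bias`, `loa_low`,
#'   `loa_high`, `frac_within`, `n`, and `points` (tibble of per-pair
#'   `mean` and `diff`).
#' @export
bland_altman <- function(q, r, loa_mult = 1.96) {
  if (length(q) != length(r)) {
    gc_abort("`q` and `r` must have equal length.", "gc_shape_error")
  }
  ok <- is.finite(q) & is.finite(r)
  q <- q[ok]; r <- r[ok]
  if (length(q) < 3) {
    gc_abort("Need at least 3 complete pairs.", "gc_insufficient_data")
  }
  d <- q - r
  bias <- mean(d)
  s <- sd(d)
  loa_low <- bias - loa_mult * s
  loa_high <- bias + loa_mult * s
  structure(list(bias = bias, loa_low = loa_low, loa_high = loa_high,
                 frac_within = mean(d >= loa_low & d <= loa_high),
                 n = length(d),
                 points = tibble::tibble(mean = (q + r) / 2, diff = d)),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("<bland_altman> n = %d, bias = %.4g, LoA [%.4g, %.4g], %.1f%% within\n",
              x$n, x$bias, x$loa_low, x$loa_high, 100 * x$frac_within))
  invisible(x)
}

#' Dynamic time warping similarity with a Sakoe-Chiba band
#'
#' Aligns two min-max-normalized series by dynamic programming with
#' absolute-difference local cost and steps (1,0), (0,1), (1,1),
#' constrained to a Sakoe-Chiba band of half-width
#' `ceil(band_frac * max(length))` around the (scaled) diagonal. The
#' cumulative distance is the sum of local costs along the optimal path;
#' the normalized similarity is `1 - distance / path_length` (path length
#' in nodes), which lies in `[0, 1]` because inputs in `[0, 1]` bound
#' each local cost by 1. `denominator = "lengths"` divides by the summed
#' series lengths instead.
#'
#' @param q,r Numeric series with values in `[0, 1]`.
#' @param band_frac Band half-width as a fraction of the longer series
#'   (default 0.2).
#' @param denominator `"path"` (default) or `"lengths"`.
#' @return A `dtw_result`: list with `cumulative_distance`, `similarity`,
#'   `path` (tibble `i`, `j`), `band_frac`, `band_halfwidth`.
#' @export
dtw_similarity <- function(q, r, band_frac = 0.2,
                           denominator = c("path", "lengths")) {
  denominator <- match.arg(denominator)
  q <- as.numeric(q); r <- as.numeric(r)
  if (length(q) == 0 || length(r) == 0 || anyNA(q) || anyNA(r)) {
    gc_abort("Both series must be non-empty with no missing values.",
             "gc_invalid_parameter")
  }
  if (any(q < -1e-9 | q > 1 + 1e-9) || any(r < -1e-9 | r > 1 + 1e-9)) {
    gc_abort("Series must be min-max normalized to [0, 1].",
             "gc_invalid_parameter")
  }
  n <- length(q); m <- length(r)
  w <- ceiling(band_frac * max(n, m))
  # symmetric band criterion: |i*m - j*n| scaled by the longer length
  in_band <- function(i, j) {
    abs(i * m - j * n) <= w * max(n, m) + 1e-9
  }
  D <- matrix(Inf, n, m)
  for (i in 1:n) {
    for (j in 1:m) {
      if (!in_band(i, j)) next
      cost <- abs(q[i] - r[j])
      best <- if (i == 1 && j == 1) 0 else {
        min(if (i > 1) D[i - 1, j] else Inf,
            if (j > 1) D[i, j - 1] else Inf,
            if (i > 1 && j > 1) D[i - 1, j - 1] else Inf)
      }
      D[i, j] <- cost + best
    }
  }
  if (!is.finite(D[n, m])) {
    gc_abort("Sakoe-Chiba band too narrow to connect the series corners.",
             "gc_infeasible_band")
  }
  # backtrack
  path <- list(c(n, m))
  i <- n; j <- m
  while (i > 1 || j > 1) {
    opts <- list()
    if (i > 1 && j > 1) opts$diag <- D[i - 1, j - 1]
    if (i > 1) opts$up <- D[i - 1, j]
    if (j > 1) opts$left <- D[i, j - 1]
    pick <- names(opts)[which.min(unlist(opts))]
    if (pick == "diag") { i <- i - 1; j <- j - 1 }
    else if (pick == "up") i <- i - 1
    else j <- j - 1
    path[[length(path) + 1]] <- c(i, j)
  }
  path <- do.call(rbind, rev(path))
  plen <- nrow(path)
  denom <- if (denominator == "path") plen else (n + m)
  structure(list(cumulative_distance = D[n, m],
                 similarity = 1 - D[n, m] / denom,
                 path = tibble::tibble(i = path[, 1], j = path[, 2]),
                 band_frac = band_frac, band_halfwidth = w),
            class = "dtw_result")
}

#' @export
print.dtw_result <- function(x, ...) {
  cat(sprintf("<dtw_result> distance %.4g, similarity %.3f (band %.0f%%, halfwidth %d)\n",
              x$cumulative_distance, x$similarity, 100 * x$band_frac,
              x$band_halfwidth))
  invisible(x)
}

#' Mann-Whitney U test
#'
#' Rank-sum test with midranks for ties; `U = min(U1, U2)` is reported.
#' The two-sided p-value is exact (complete enumeration of rank
#' assignments) for `n1 + n2 <= 20` and otherwise uses the tie-corrected
#' normal approximation with continuity correction.
#'
#' @param a,b Non-empty numeric samples.
#' @return A one-row tibble: `u`, `p_value`, `n_a`, `n_b`, `method`.
#' @export
mann_whitney_u <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  n1 <- length(a); n2 <- length(b)
  if (n1 == 0 || n2 == 0) {
    gc_abort("Both samples must be non-empty.", "gc_insufficient_data")
  }
  pooled <- c(a, b)
  rk <- rank(pooled)
  u1 <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  u2 <- n1 * n2 - u1
  u <- min(u1, u2)
  if (n1 + n2 <= 20) {
    method <- "exact enumeration"
    combs <- utils::combn(n1 + n2, n1)
    us <- apply(combs, 2, function(ix) {
      u1p <- sum(rk[ix]) - n1 * (n1 + 1) / 2
      min(u1p, n1 * n2 - u1p)
    })
    p <- mean(us <= u + 1e-9)
  } else {
    method <- "normal approximation"
    N <- n1 + n2
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (u - n1 * n2 / 2 + 0.5) / sqrt(sigma2)
      p <- min(1, 2 * pnorm(z))
    }
  }
  tibble::tibble(u = u, p_value = p, n_a = n1, n_b = n2, method = method)
}
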