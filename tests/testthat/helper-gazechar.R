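# Shared fixtures and independent oracles, all built in code.

study_geom <- screen_geometry()  # 1600 x 900, 55.9 cm diagonal, 60 cm

# A gaze stream at a fixed position (or along supplied coordinates).
make_stream <- function(x, y, rate_hz = 100, valid = TRUE,
                        geometry = study_geom) {
  n <- max(length(x), length(y))
  x <- rep_len(x, n); y <- rep_len(y, n)
  gaze_stream(tibble::tibble(t_s = (seq_len(n) - 1) / rate_hz,
                             x_px = x, y_px = y,
                             valid = rep_len(valid, n)),
              geometry = geometry, rate_hz = rate_hz)
}

# One synthetic sample block per grid cell with the requested counts.
grid_stream <- function(per_cell, geometry = study_geom, cell = 100) {
  ncx <- ceiling(geometry$width_px / cell)
  ncy <- ceiling(geometry$height_px / cell)
  stopifnot(length(per_cell) == ncx * ncy)
  xs <- ys <- numeric(0)
  k <- 1
  for (cy in 1:ncy) for (cx in 1:ncx) {
    m <- per_cell[k]; k <- k + 1
    if (m > 0) {
      xs <- c(xs, rep((cx - 0.5) * cell, m))
      ys <- c(ys, rep((cy - 0.5) * cell, m))
    }
  }
  o <- sample(length(xs))
  make_stream(xs[o], ys[o])
}

# ---- independent oracles -------------------------------------------------

# DTW minimum cumulative cost by plain top-down recursion over the three
# admissible steps (no tabulation reuse across tests; memoization within
# one call keeps it tractable at length <= 12).
oracle_dtw_cost <- function(q, r, band_frac = 0.2) {
  n <- length(q); m <- length(r)
  w <- ceiling(band_frac * max(n, m))
  memo <- matrix(NA_real_, n, m)
  rec <- function(i, j) {
    if (abs(i * m - j * n) > w * max(n, m) + 1e-9) return(Inf)
    if (!is.na(memo[i, j])) return(memo[i, j])
    cost <- abs(q[i] - r[j])
    prev <- if (i == 1 && j == 1) 0 else {
      min(if (i > 1) rec(i - 1, j) else Inf,
          if (j > 1) rec(i, j - 1) else Inf,
          if (i > 1 && j > 1) rec(i - 1, j - 1) else Inf)
    }
    memo[i, j] <<- cost + prev
    memo[i, j]
  }
  rec(n, m)
}

# Full enumeration of every admissible warp path (tiny sizes only).
oracle_dtw_enumerate <- function(q, r, band_frac = 0.2) {
  n <- length(q); m <- length(r)
  w <- ceiling(band_frac * max(n, m))
  in_band <- function(i, j) abs(i * m - j * n) <= w * max(n, m) + 1e-9
  best <- Inf
  walk <- function(i, j, acc) {
    if (!in_band(i, j)) return(invisible(NULL))
    acc <- acc + abs(q[i] - r[j])
    if (i == n && j == m) {
      best <<- min(best, acc)
      return(invisible(NULL))
    }
    if (i < n) walk(i + 1, j, acc)
    if (j < m) walk(i, j + 1, acc)
    if (i < n && j < m) walk(i + 1, j + 1, acc)
    invisible(NULL)
  }
  walk(1, 1, 0)
  best
}

# Two-way ANOVA mean squares by explicit elementwise loops.
oracle_icc31 <- function(x) {
  n <- nrow(x); k <- ncol(x)
  grand <- 0
  for (i in 1:n) for (j in 1:k) grand <- grand + x[i, j]
  grand <- grand / (n * k)
  ssr <- 0
  for (i in 1:n) {
    rm <- 0
    for (j in 1:k) rm <- rm + x[i, j]
    rm <- rm / k
    ssr <- ssr + k * (rm - grand)^2
  }
  ssc <- 0
  for (j in 1:k) {
    cm <- 0
    for (i in 1:n) cm <- cm + x[i, j]
    cm <- cm / n
    ssc <- ssc + n * (cm - grand)^2
  }
  sst <- 0
  for (i in 1:n) for (j in 1:k) sst <- sst + (x[i, j] - grand)^2
  msr <- ssr / (n - 1)
  mse <- (sst - ssr - ssc) / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse)
}

# Mann-Whitney by direct enumeration of which pooled positions belong to
# sample a; midranks throughout.
oracle_mann_whitney <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  rk <- rank(c(a, b))
  stat <- function(ix) {
    u1 <- sum(rk[ix]) - n1 * (n1 + 1) / 2
    min(u1, n1 * n2 - u1)
  }
  u_obs <- stat(seq_len(n1))
  all_u <- apply(utils::combn(n1 + n2, n1), 2, stat)
  list(u = u_obs, p = mean(all_u <= u_obs + 1e-9))
}

# Saccade-threshold fixed point by a fresh iteration written separately.
oracle_fixed_point <- function(v, init, mult) {
  pt <- init
  repeat {
    sub <- v[v <= pt]
    new_pt <- mean(sub) + mult * stats::sd(sub)
    if (abs(new_pt - pt) < 1) return(new_pt)
    pt <- new_pt
  }
}
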