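#' Corner correspondence between scene-camera and screen coordinates
#'
#' Pairs the four screen-corner positions as seen in the scene camera
#' (e.g. extracted fiducial-marker corners) with their known screen-pixel
#' positions. Exactly four pairs are required and no three scene corners
#' may be collinear.
#'
#' @param scene_corners,screen_corners 4 x 2 matrices (or data frames with
#'   columns `x`, `y`) of corner coordinates, in corresponding order.
#' @return An object of class `corner_correspondence`.
#' @export
corner_correspondence <- function(scene_corners, screen_corners) {
  as_pts <- function(p, name) {
    if (is.data.frame(p)) p <- as.matrix(p[, c("x", "y")])
    p <- unname(as.matrix(p))
    if (!is.numeric(p) || !identical(dim(p), c(4L, 2L)) || anyNA(p)) {
      gc_abort(sprintf("`%s` must be four finite 2D points.", name),
               "gc_degenerate_correspondence")
    }
    p
  }
  scene <- as_pts(scene_corners, "scene_corners")
  screen <- as_pts(screen_corners, "screen_corners")
  if (any_three_collinear(scene)) {
    gc_abort("Three scene corners are collinear; correspondence is degenerate.",
             "gc_degenerate_correspondence")
  }
  structure(list(scene = scene, screen = screen),
            class = "corner_correspondence")
}

any_three_collinear <- function(p) {
  scale <- max(abs(p)) + 1
  for (idx in utils::combn(4, 3, simplify = FALSE)) {
    a <- p[idx[1], ]; b <- p[idx[2], ]; c <- p[idx[3], ]
    cross <- (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
    if (abs(cross) < 1e-9 * scale^2) return(TRUE)
  }
  FALSE
}

# 4-point direct linear transform. Returns the 3x3 homography H mapping
# scene -> screen, normalized so that its Frobenius norm is 1.
fit_homography <- function(corr) {
  s <- corr$scene; d <- corr$screen
  A <- matrix(0, 8, 9)
  for (i in 1:4) {
    x <- s[i, 1]; y <- s[i, 2]; u <- d[i, 1]; v <- d[i, 2]
    A[2 * i - 1, ] <- c(-x, -y, -1, 0, 0, 0, u * x, u * y, u)
    A[2 * i, ]     <- c(0, 0, 0, -x, -y, -1, v * x, v * y, v)
  }
  h <- svd(A, nu = 0, nv = 9)$v[, 9]
  H <- matrix(h, 3, 3, byrow = TRUE)
  H / sqrt(sum(H^2))
}

#' Map scene-camera gaze points onto the screen
#'
#' Fits the planar projective transform (homography) that maps the four
#' scene corners exactly onto the four screen corners, applies it to the
#' supplied points, and flags points that land outside the screen bounds.
#'
#' @param points A data frame with columns `x`, `y` (scene-camera pixels).
#' @param corr A [corner_correspondence()].
#' @param geometry A [screen_geometry()] defining the screen bounds used
#'   for the `off_screen` flag.
#' @return A tibble with columns `x_px`, `y_px`, `off_screen`.
#' @export
scene_to_screen <- function(points, corr, geometry = screen_geometry()) {
  if (!inherits(corr, "corner_correspondence")) {
    gc_abort("`corr` must be a `corner_correspondence`.",
             "gc_degenerate_correspondence")
  }
  check_geometry(geometry)
  check_columns(points, c("x", "y"), "`points`")
  H <- fit_homography(corr)
  P <- rbind(t(as.matrix(points[, c("x", "y")])), 1)
  Q <- H %*% P
  x <- Q[1, ] / Q[3, ]
  y <- Q[2, ] / Q[3, ]
  tibble::tibble(
    x_px = x, y_px = y,
    off_screen = x < 0 | x > geometry$width_px | y < 0 | y > geometry$height_px
  )
}
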