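# Closing a sparse, unordered set of contour pixels into a 1-pixel closed
# line. The averaging fusion algorithms emit isolated consensus pixels; to
# connect them each pixel needs neighbours, which are hard to identify in the
# Cartesian plane. All four closers therefore reason about the points around
# a common reference centre: the interpolation closers order them by angle
# and treat radius as a function of angle, the active-contour closers shrink
# a curve onto them.

#' Sparse contour point set
#'
#' @param points An n x 2 matrix (or data frame) of (row, col) pixel
#'   coordinates; at least 3 distinct points.
#' @param center Continuous (row, col) reference point for the polar
#'   conversion; defaults to the centroid of the points. The fusion layer
#'   passes the centroid of the filled union of the input segmentations.
#' @param dim Canvas dimensions `c(H, W)` for rasterized output; defaults to
#'   a tight canvas with a 3-pixel margin.
#' @return An object of class `sparse_points`.
#' @export
sparse_points <- function(points, center = NULL, dim = NULL) {
  points <- as.matrix(points)
  if (ncol(points) != 2L) sf_abort("points must be an n x 2 (row, col) matrix",
                                   "segfuse_format_error")
  points <- unique(round(points))
  storage.mode(points) <- "integer"
  if (nrow(points) < 3L) {
    sf_abort(sprintf("need at least 3 distinct points, got %d", nrow(points)),
             "segfuse_degenerate_error")
  }
  if (is.null(center)) center <- colMeans(points)
  if (any(!is.finite(center))) sf_abort("center must be finite", "segfuse_degenerate_error")
  if (is.null(dim)) dim <- c(max(points[, 1]) + 3L, max(points[, 2]) + 3L)
  structure(list(points = points, center = as.numeric(center), dim = as.integer(dim)),
            class = "sparse_points")
}

as_sparse_points <- function(x, ...) {
  if (inherits(x, "sparse_points")) x else sparse_points(x, ...)
}

point_polar <- function(points, center) {
  dr <- center[1] - points[, 1]          # +row is down; angles run CCW from +col
  dc <- points[, 2] - center[2]
  theta <- atan2(dr, dc) %% (2 * pi)
  r <- sqrt(dr^2 + dc^2)
  list(theta = theta, r = r)
}

#' Order contour points by angle around the centre
#'
#' Converts the points to polar coordinates about the reference centre and
#' sorts them by angle. Points whose angles collide (within 1e-9 rad) are
#' merged by averaging their radii, keeping the radius single-valued as a
#' function of angle.
#'
#' @param points A [sparse_points] object (or coercible point matrix).
#' @return A list with `theta` (strictly increasing in `[0, 2*pi)`), `r`,
#'   and `center`, of class `polar_points`.
#' @export
order_polar <- function(points) {
  sp <- as_sparse_points(points)
  pol <- point_polar(sp$points, sp$center)
  if (all(pol$r < 1e-9)) {
    sf_abort("all points coincide with the centre; no angular ordering exists",
             "segfuse_degenerate_error")
  }
  key <- round(pol$theta / 1e-9)
  agg_r <- vapply(split(pol$r, key), mean, numeric(1))
  agg_t <- vapply(split(pol$theta, key), function(t) t[1], numeric(1))
  o <- order(agg_t)
  structure(list(theta = unname(agg_t[o]), r = unname(agg_r[o]), center = sp$center),
            class = "polar_points")
}

#' Linear interpolant between two points
#'
#' The two-point straight-line interpolant used by the linear closing method:
#' `f(x) = (x1 - x)/(x1 - x0) * y0 + (x - x0)/(x1 - x0) * y1`.
#'
#' @param x Evaluation abscissa(s).
#' @param x0,y0 First point.
#' @param x1,y1 Second point.
#' @return `f(x)`.
#' @examples
#' linear_interp(1, 0, 0, 2, 4)  # 2
#' @export
linear_interp <- function(x, x0, y0, x1, y1) {
  (x1 - x) / (x1 - x0) * y0 + (x - x0) / (x1 - x0) * y1
}

finalize_closed_line <- function(px, input_px, mode = "middle") {
  px <- px | input_px
  px <- thin_zs(px, protect = input_px)
  new_contour_line(px, mode)
}

input_px_matrix <- function(sp) {
  px <- matrix(FALSE, sp$dim[1], sp$dim[2])
  keep <- sp$points[, 1] >= 1 & sp$points[, 1] <= sp$dim[1] &
    sp$points[, 2] >= 1 & sp$points[, 2] <= sp$dim[2]
  px[sp$points[keep, , drop = FALSE]] <- TRUE
  px
}

#' Close sparse contour points with straight segments
#'
#' The points are sorted by angle about the centre and consecutive points
#' (cyclically, last joined back to first) are connected by rasterized
#' straight segments. All input pixels are preserved in the output; the
#' result is thinned to a one-pixel line without ever deleting an input
#' pixel.
#'
#' @param points A [sparse_points] object (or point matrix).
#' @return A `contour_line` on the point set's canvas.
#' @export
close_linear <- function(points) {
  sp <- as_sparse_points(points)
  pol <- point_polar(sp$points, sp$center)
  if (all(pol$r < 1e-9)) {
    sf_abort("all points coincide with the centre", "segfuse_degenerate_error")
  }
  o <- order(pol$theta, pol$r)
  verts <- sp$points[o, , drop = FALSE]
  px <- rasterize_closed_path(verts, sp$dim, closed = TRUE)
  finalize_closed_line(px, input_px_matrix(sp))
}

#' Close sparse contour points with shape-preserving interpolation
#'
#' Monotone piecewise-cubic Hermite (PCHIP) interpolation of the radius as a
#' periodic function of the angle. The interpolant passes through every
#' sample (`P(x_j) = y_j`) and preserves monotonicity, so the closed curve
#' never overshoots the radii of the bracketing points. This is the default
#' closing method.
#'
#' @param points A [sparse_points] object (or point matrix).
#' @return A `contour_line` on the point set's canvas.
#' @export
close_pchip <- function(points) {
  sp <- as_sparse_points(points)
  po <- order_polar(sp)
  k <- length(po$theta)
  if (k < 3L) {
    sf_abort("fewer than 3 distinct angular samples; cannot interpolate a closed curve",
             "segfuse_degenerate_error")
  }
  # wrap three samples on each side so the periodic seam is interpolated
  # with interior (not one-sided) slopes
  nw <- min(3L, k - 1L)
  xi <- c(utils::tail(po$theta, nw) - 2 * pi, po$theta, utils::head(po$theta, nw) + 2 * pi)
  yi <- c(utils::tail(po$r, nw), po$r, utils::head(po$r, nw))
  to_cart <- function(theta, r) {
    cbind(sp$center[1] - r * sin(theta), sp$center[2] + r * cos(theta))
  }
  # the curve visits every sample; the interpolant is only evaluated across
  # gaps wider than a pixel step, so already-adjacent points are connected
  # directly and a dense input ring is retraced instead of resampled
  verts <- NULL
  for (j in seq_len(k)) {
    ta <- po$theta[j]
    tb <- if (j < k) po$theta[j + 1] else po$theta[1] + 2 * pi
    rb <- if (j < k) po$r[j + 1] else po$r[1]
    pa <- to_cart(ta, po$r[j])
    pb <- to_cart(tb, rb)
    verts <- rbind(verts, pa)
    gap <- sqrt(sum((pa - pb)^2))
    if (gap > 1.5) {
      nseg <- ceiling(2 * gap)
      ts <- seq(ta, tb, length.out = nseg + 1L)[-c(1L, nseg + 1L)]
      verts <- rbind(verts, to_cart(ts, pracma::pchip(xi, yi, ts)))
    }
  }
  px <- rasterize_closed_path(verts, sp$dim, closed = TRUE)
  finalize_closed_line(px, input_px_matrix(sp))
}

#' Close sparse contour points with a morphological active contour
#'
#' Builds an energy image from the Euclidean distance transform of the point
#' set, initializes the curve at the filled convex hull of the points, and
#' evolves it with the chosen morphological active-contour scheme
#' (`chan_vese`: region-based, on a gap-closed guide image; `geodesic`: a
#' shrinking balloon stopped by an inverse-distance edge map). Unlike the
#' interpolation closers, input pixels are not guaranteed to lie on the
#' output.
#'
#' @param points A [sparse_points] object (or point matrix).
#' @param method `"chan_vese"` or `"geodesic"`.
#' @param iterations Number of evolution steps (default 100); 0 returns the
#'   boundary of the convex-hull initialization.
#' @param smoothing Number of morphological curvature-smoothing passes per
#'   step (default 1).
#' @return A `contour_line` (internal boundary of the evolved region).
#' @export
close_active_contour <- function(points, method = c("chan_vese", "geodesic"),
                                 iterations = 100L, smoothing = 1L) {
  method <- match.arg(method)
  sp <- as_sparse_points(points)
  pts_px <- input_px_matrix(sp)
  init <- convex_hull_region(sp)
  if (!is_closed_px(internal_boundary_px(init)) && sum(init) < 3) {
    sf_abort("degenerate (collinear) point set: no enclosed region to evolve",
             "segfuse_degenerate_error")
  }
  u <- init
  if (iterations > 0) {
    if (method == "chan_vese") {
      guide <- chan_vese_guide(pts_px)
      u <- morph_acwe(guide, u, iterations = iterations, smoothing = smoothing)
    } else {
      # stopping function: ~0 on the contour points, -> 1 away from them
      d <- dist_to_px(pts_px)
      g <- 1 - 1 / (1 + (d / 2)^2)
      u <- morph_gac(g, u, iterations = iterations, smoothing = smoothing,
                     balloon = -1, threshold = 0.3)
    }
  }
  region <- fill_holes_px(u)
  if (!any(region)) {
    sf_abort("active contour collapsed to an empty region; try fewer iterations",
             "segfuse_convergence_error")
  }
  region <- largest_component(region)
  line <- internal_boundary_px(region)
  if (!is_closed_px(line) && sum(region) <= nrow(sp$points)) {
    sf_abort("active contour degenerated to a line; the point set may be collinear",
             "segfuse_degenerate_error")
  }
  new_contour_line(thin_zs(line), "internal")
}

convex_hull_region <- function(sp) {
  pts <- sp$points
  hull <- grDevices::chull(pts[, 2], pts[, 1])   # chull takes x = col, y = row
  if (length(hull) < 3L) {
    sf_abort("degenerate (collinear) point set: convex hull has no interior",
             "segfuse_degenerate_error")
  }
  ring <- rasterize_closed_path(pts[hull, , drop = FALSE], sp$dim, closed = TRUE)
  fill_holes_px(ring)
}

# Gap-close the sparse points into a filled region to guide Chan-Vese:
# dilate until filling creates an interior, fill, then erode back.
chan_vese_guide <- function(pts_px) {
  for (k in 1:12) {
    d <- dilate_sq(pts_px, k)
    f <- fill_holes_px(d)
    if (sum(f) > sum(d)) {
      region <- erode_sq(f, k)
      if (!any(region)) region <- f
      g <- matrix(as.numeric(region), nrow(region))
      # light box blur to give the region-based energy a usable gradient
      for (i in 1:2) {
        g <- (g +
                nbr_mat(g, -1, 0, 0) + nbr_mat(g, 1, 0, 0) +
                nbr_mat(g, 0, -1, 0) + nbr_mat(g, 0, 1, 0) +
                nbr_mat(g, -1, -1, 0) + nbr_mat(g, -1, 1, 0) +
                nbr_mat(g, 1, -1, 0) + nbr_mat(g, 1, 1, 0)) / 9
      }
      return(g)
    }
  }
  sf_abort("point set too sparse or degenerate: no closed region can be formed",
           "segfuse_degenerate_error")
}
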