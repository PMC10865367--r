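# Synthetic fixtures: ground-truth shapes plus simulated raters with
# controlled disagreement, so every fusion algorithm can be exercised and
# benchmarked without any external imaging data.

#' Specification of a synthetic ground-truth shape
#'
#' @param kind `"disk"`, `"ellipse"` or `"blob"` (a disk whose radius is
#'   modulated by random low-order harmonics).
#' @param canvas Canvas dimensions `c(H, W)` (default 64 x 64).
#' @param radius Disk radius (pixels).
#' @param semi_axes Ellipse semi-axes `c(row, col)` (pixels).
#' @param mean_radius,amplitudes Blob mean radius and relative harmonic
#'   amplitudes (harmonic k = 2, 3, ... per entry); phases are drawn from
#'   `seed`.
#' @param seed RNG seed (used by `blob` only).
#' @return An object of class `shape_spec`.
#' @export
shape_spec <- function(kind = c("disk", "ellipse", "blob"), canvas = c(64, 64),
                       radius = 20, semi_axes = c(20, 12), mean_radius = 18,
                       amplitudes = c(0.12, 0.08), seed = 0L) {
  kind <- match.arg(kind)
  spec <- structure(list(kind = kind, canvas = as.integer(canvas), radius = radius,
                         semi_axes = semi_axes, mean_radius = mean_radius,
                         amplitudes = amplitudes, seed = as.integer(seed)),
                    class = "shape_spec")
  max_extent <- switch(kind,
    disk = radius,
    ellipse = max(semi_axes),
    blob = mean_radius * (1 + sum(abs(amplitudes)))
  )
  # the external one-pixel ring must fit: keep a 2-pixel margin
  if (max_extent + 2 > min((canvas - 1) / 2)) {
    sf_abort(sprintf("shape of extent %.1f px does not fit a %dx%d canvas with a 2-pixel margin",
                     max_extent, canvas[1], canvas[2]), "segfuse_spec_error")
  }
  spec
}

canvas_polar <- function(canvas) {
  ctr <- (canvas + 1) / 2
  rows <- matrix(seq_len(canvas[1]), canvas[1], canvas[2])
  cols <- matrix(seq_len(canvas[2]), canvas[1], canvas[2], byrow = TRUE)
  dr <- ctr[1] - rows
  dc <- cols - ctr[2]
  list(theta = atan2(dr, dc) %% (2 * pi), r = sqrt(dr^2 + dc^2), center = ctr)
}

#' Rasterize a synthetic ground-truth region
#'
#' Deterministic given the spec (including its seed). All built-in kinds are
#' star-shaped about the canvas centre, which [perturb_boundary()] relies on.
#'
#' @param spec A [shape_spec].
#' @return A `region_mask`.
#' @examples
#' sum(make_shape(shape_spec("disk", radius = 20))$px) / (pi * 20^2)  # ~1
#' @export
make_shape <- function(spec) {
  pol <- canvas_polar(spec$canvas)
  px <- switch(spec$kind,
    disk = pol$r <= spec$radius,
    ellipse = {
      ctr <- pol$center
      rows <- matrix(seq_len(spec$canvas[1]), spec$canvas[1], spec$canvas[2])
      cols <- matrix(seq_len(spec$canvas[2]), spec$canvas[1], spec$canvas[2], byrow = TRUE)
      ((rows - ctr[1]) / spec$semi_axes[1])^2 + ((cols - ctr[2]) / spec$semi_axes[2])^2 <= 1
    },
    blob = {
      phases <- withr::with_seed(spec$seed, stats::runif(length(spec$amplitudes), 0, 2 * pi))
      rtheta <- spec$mean_radius * (1 + Reduce(`+`, lapply(seq_along(spec$amplitudes),
        function(k) spec$amplitudes[k] * cos((k + 1) * pol$theta + phases[k])), 0))
      pol$r <= rtheta
    }
  )
  new_region_mask(fill_holes_px(px))
}

#' Specification of a simulated rater
#'
#' Two disagreement models:
#' * `boundary`: the rater redraws the boundary, displacing the radius
#'   `r(theta)` by smooth zero-mean noise (a truncated Fourier series with
#'   `smoothness` harmonics, scaled so the maximum displacement equals
#'   `amplitude` pixels) — this emulates inter-rater contour variability;
#' * `bernoulli`: the rater corrupts the truth per pixel, keeping a
#'   foreground pixel with probability `p` (sensitivity) and a background
#'   pixel with probability `q` (specificity) — exactly the generative model
#'   STAPLE assumes, so the true `(p, q)` are known.
#'
#' @param mode `"boundary"` or `"bernoulli"`.
#' @param amplitude Maximum radial displacement in pixels (boundary mode).
#' @param smoothness Number of Fourier harmonics in the radial noise
#'   (boundary mode; fewer = smoother).
#' @param p,q Sensitivity and specificity (bernoulli mode).
#' @param seed RNG seed for this rater.
#' @return An object of class `rater_spec`.
#' @export
rater_spec <- function(mode = c("boundary", "bernoulli"), amplitude = 2,
                       smoothness = 3L, p = 0.9, q = 0.98, seed = 0L) {
  mode <- match.arg(mode)
  if (amplitude < 0) sf_abort("amplitude must be >= 0", "segfuse_spec_error")
  if (p < 0 || p > 1 || q < 0 || q > 1) {
    sf_abort("p and q must lie in [0, 1]", "segfuse_spec_error")
  }
  structure(list(mode = mode, amplitude = amplitude, smoothness = as.integer(smoothness),
                 p = p, q = q, seed = as.integer(seed)),
            class = "rater_spec")
}

# Periodic radius profile r(theta) of a star-shaped region about its centroid.
radius_profile <- function(px, center) {
  b <- which(internal_boundary_px(px), arr.ind = TRUE)
  dr <- center[1] - b[, 1]
  dc <- b[, 2] - center[2]
  theta <- atan2(dr, dc) %% (2 * pi)
  r <- sqrt(dr^2 + dc^2)
  o <- order(theta)
  theta <- theta[o]
  r <- r[o]
  keep <- c(TRUE, diff(theta) > 1e-12)
  theta <- theta[keep]
  r <- r[keep]
  xs <- c(theta[length(theta)] - 2 * pi, theta, theta[1] + 2 * pi)
  ys <- c(r[length(r)], r, r[1])
  stats::approxfun(xs, ys)
}

#' Perturb a region's boundary radially
#'
#' Simulates one boundary-mode rater: the radius of the (star-shaped) region
#' about its centroid is displaced by smooth zero-mean noise whose maximum
#' displacement is `spec$amplitude` pixels. `amplitude = 0` returns the
#' region unchanged.
#'
#' @param region A `region_mask` (star-shaped about its centroid).
#' @param spec A [rater_spec] in boundary mode.
#' @return A [binary_mask].
#' @export
perturb_boundary <- function(region, spec) {
  px <- as_px(region)
  if (spec$amplitude == 0) return(binary_mask(px))
  idx <- which(px, arr.ind = TRUE)
  center <- colMeans(idx)
  r_of <- radius_profile(px, center)
  K <- max(1L, spec$smoothness)
  # truncated Fourier series including the constant term: a rater can be
  # systematically biased outward or inward (the dominant real inter-rater
  # effect) as well as locally wobbly; the bias is zero-mean across raters
  coefs <- withr::with_seed(spec$seed, list(
    c = stats::runif(K + 1L, -1, 1),
    phi = stats::runif(K, 0, 2 * pi)
  ))
  delta <- function(theta) {
    Reduce(`+`, lapply(seq_len(K), function(k) coefs$c[k + 1L] * cos(k * theta + coefs$phi[k])),
           coefs$c[1] + 0 * theta)
  }
  tg <- seq(0, 2 * pi, length.out = 720)
  m <- max(abs(delta(tg)))
  scale <- if (m > 0) spec$amplitude / m else 0
  h <- nrow(px)
  w <- ncol(px)
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  dr <- center[1] - rows
  dc <- cols - center[2]
  theta <- atan2(dr, dc) %% (2 * pi)
  rr <- sqrt(dr^2 + dc^2)
  out <- rr <= r_of(theta) + scale * delta(theta)
  out <- fill_holes_px(out)
  if (!any(out)) {
    sf_abort("boundary perturbation erased the region (amplitude too large)",
             "segfuse_degenerate_error")
  }
  out <- largest_component(out)
  binary_mask(out)
}

#' Simulate a set of raters for a ground-truth region
#'
#' Boundary-mode raters perturb the boundary with [perturb_boundary()];
#' bernoulli-mode raters flip each pixel independently (foreground kept with
#' probability `p`, background kept with probability `q`), after which the
#' largest component is kept and holes are filled so every output satisfies
#' the single-object mask invariants. The raw (uncleaned) bernoulli flip
#' fields are attached as `attr(, "raw")`, one per rater (`NULL` for
#' boundary raters): STAPLE's performance parameters can be estimated
#' against exactly the generative model on them.
#'
#' @param region The ground-truth `region_mask`.
#' @param specs List of at least two [rater_spec]s.
#' @return A [segmentation_set] with a `raw` attribute.
#' @export
simulate_raters <- function(region, specs) {
  if (length(specs) < 2L) {
    sf_abort("need at least 2 rater specs", "segfuse_arity_error")
  }
  px <- as_px(region)
  raw <- vector("list", length(specs))
  masks <- vector("list", length(specs))
  for (i in seq_along(specs)) {
    spec <- specs[[i]]
    if (spec$mode == "boundary") {
      masks[[i]] <- perturb_boundary(region, spec)
    } else {
      field <- withr::with_seed(spec$seed, {
        u <- matrix(stats::runif(length(px)), nrow(px))
        (px & u <= spec$p) | (!px & u > spec$q)
      })
      raw[[i]] <- field
      clean <- fill_holes_px(largest_component(field))
      if (!any(clean)) {
        sf_abort(sprintf("rater %d produced an empty segmentation", i),
                 "segfuse_degenerate_error")
      }
      masks[[i]] <- binary_mask(clean)
    }
  }
  out <- segmentation_set(masks)
  attr(out, "raw") <- raw
  out
}
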