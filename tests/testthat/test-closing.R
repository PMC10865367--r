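test_that("the two-point linear interpolant is exact at the knots and midpoint", {
  expect_equal(linear_interp(1, 0, 0, 2, 4), 2)
  withr::with_seed(42, {
    x0 <- runif(1000, -50, 50)
    x1 <- x0 + runif(1000, 0.1, 20)
    y0 <- runif(1000, -50, 50)
    y1 <- runif(1000, -50, 50)
  })
  expect_equal(linear_interp(x0, x0, y0, x1, y1), y0, tolerance = 1e-12)
  expect_equal(linear_interp(x1, x0, y0, x1, y1), y1, tolerance = 1e-12)
  expect_equal(linear_interp((x0 + x1) / 2, x0, y0, x1, y1), (y0 + y1) / 2,
               tolerance = 1e-12)
})

test_that("order_polar sorts by angle and merges same-angle collisions", {
  # axis points about centre (5, 5): angles 0, pi/2, pi, 3pi/2 at r = 1
  pts <- rbind(c(5, 6), c(4, 5), c(5, 4), c(6, 5))
  po <- order_polar(sparse_points(pts, center = c(5, 5)))
  expect_equal(po$theta, c(0, pi / 2, pi, 3 * pi / 2))
  expect_equal(po$r, rep(1, 4))
  # duplicated point collapses to one sample
  po2 <- order_polar(sparse_points(rbind(pts, c(5, 6)), center = c(5, 5)))
  expect_equal(length(po2$theta), 4)
  # two points at the same angle, r = 4 and 6, average to r = 5
  pts3 <- rbind(c(5, 9), c(5, 11), c(4, 5), c(6, 5))
  po3 <- order_polar(sparse_points(pts3, center = c(5, 5)))
  expect_equal(po3$r[po3$theta == 0], 5)
  # all points at the centre is degenerate
  expect_error(order_polar(sparse_points(rbind(c(5, 5), c(5, 5), c(5, 5)))),
               class = "segfuse_degenerate_error")
})

test_that("close_linear rasterizes the polar-sorted polygon", {
  # 4 corner pixels of a square about its centre: the diamond of the corners
  pts <- rbind(c(4, 4), c(4, 12), c(12, 12), c(12, 4))
  out <- close_linear(sparse_points(pts, center = c(8, 8), dim = c(16, 16)))
  expect_true(is_closed(out))
  expect_true(all(out$px[pts]))
  oracle <- oracle_chord_pixels(pts, c(16, 16))  # corners joined cyclically by angle
  expect_true(all(segfuse:::fill_holes_px(out$px) | !segfuse:::fill_holes_px(oracle)))
  # output never strays off the chord set by more than one pixel
  d <- segfuse:::dist_to_px(oracle)
  expect_lte(max(d[out$px]), sqrt(2))
})

test_that("interpolation closers reproduce a sampled circle within 1.5 px", {
  theta <- seq(0, 2 * pi, length.out = 17)[-17]
  pts <- unique(cbind(round(16 - 10 * sin(theta)), round(16 + 10 * cos(theta))))
  sp <- sparse_points(pts, center = c(16, 16), dim = c(32, 32))
  for (closer in list(close_linear, close_pchip)) {
    out <- closer(sp)
    expect_true(is_closed(out))
    expect_true(all(out$px[pts]))
    idx <- which(out$px, arr.ind = TRUE)
    radii <- sqrt((idx[, 1] - 16)^2 + (idx[, 2] - 16)^2)
    expect_lte(max(abs(radii - 10)), 1.5)          # one Hausdorff direction
    circ <- cbind(16 - 10 * sin(seq(0, 2 * pi, length.out = 360)),
                  16 + 10 * cos(seq(0, 2 * pi, length.out = 360)))
    dmin <- vapply(seq_len(nrow(circ)), function(i) {
      min(sqrt((idx[, 1] - circ[i, 1])^2 + (idx[, 2] - circ[i, 2])^2))
    }, numeric(1))
    expect_lte(max(dmin), 1.5)                     # and the other
  }
})

test_that("close_pchip interpolates constants exactly and preserves shape", {
  # constant radius 7 -> a rasterized circle of radius 7
  theta <- seq(0, 2 * pi, length.out = 13)[-13]
  pts <- unique(cbind(round(12 - 7 * sin(theta)), round(12 + 7 * cos(theta))))
  out <- close_pchip(sparse_points(pts, center = c(12, 12), dim = c(24, 24)))
  idx <- which(out$px, arr.ind = TRUE)
  radii <- sqrt((idx[, 1] - 12)^2 + (idx[, 2] - 12)^2)
  expect_lte(max(abs(radii - 7)), 1.2)
  # monotone radii over an arc stay within the bracketing samples (no overshoot)
  k <- 12
  th <- seq(0, 2 * pi, length.out = k + 1)[-(k + 1)]
  r <- seq(6, 16, length.out = k)                 # strictly increasing in theta
  pts2 <- unique(cbind(round(20 - r * sin(th)), round(20 + r * cos(th))))
  out2 <- close_pchip(sparse_points(pts2, center = c(20, 20), dim = c(40, 40)))
  po <- order_polar(sparse_points(pts2, center = c(20, 20)))
  idx2 <- which(out2$px, arr.ind = TRUE)
  th2 <- atan2(20 - idx2[, 1], idx2[, 2] - 20) %% (2 * pi)
  r2 <- sqrt((idx2[, 1] - 20)^2 + (idx2[, 2] - 20)^2)
  for (j in seq_len(length(po$theta) - 1)) {
    sel <- th2 >= po$theta[j] & th2 <= po$theta[j + 1]
    if (!any(sel)) next
    lo <- min(po$r[j], po$r[j + 1]) - 1   # 1 px rasterization slack
    hi <- max(po$r[j], po$r[j + 1]) + 1
    expect_true(all(r2[sel] >= lo & r2[sel] <= hi))
  }
  # independent monotone-cubic cross-check: base R Fritsch-Carlson interpolant
  fc <- stats::splinefun(po$theta, po$r, method = "monoH.FC")
  grid <- seq(po$theta[1], po$theta[length(po$theta)], length.out = 200)
  ours <- pracma::pchip(po$theta, po$r, grid)
  expect_lt(max(abs(ours - fc(grid))), 0.75)
})

test_that("input pixels are preserved by both interpolation closers", {
  for (seed in 1:100) {
    pts <- random_star_points(seed)
    sp <- sparse_points(pts, center = c(28, 28), dim = c(56, 56))
    lin <- close_linear(sp)
    pch <- close_pchip(sp)
    expect_true(all(lin$px[pts]), label = sprintf("linear seed %d", seed))
    expect_true(all(pch$px[pts]), label = sprintf("pchip seed %d", seed))
    expect_true(is_closed(lin))
    expect_true(is_closed(pch))
  }
})

test_that("active-contour closers recover a densely sampled circle", {
  theta <- seq(0, 2 * pi, length.out = 73)[-73]
  pts <- unique(cbind(round(24 - 12 * sin(theta)), round(24 + 12 * cos(theta))))
  sp <- sparse_points(pts, center = c(24, 24), dim = c(48, 48))
  truth <- disk_px(48, 48, 24, 24, 12)
  for (method in c("chan_vese", "geodesic")) {
    out <- close_active_contour(sp, method)
    expect_true(is_closed(out), label = method)
    ji <- oracle_jaccard(segfuse:::fill_holes_px(out$px), truth)
    expect_gte(ji, 0.9)
  }
})

test_that("active contour with zero iterations returns the convex hull boundary", {
  pts <- rbind(c(5, 5), c(5, 20), c(20, 20), c(20, 5), c(12, 12))
  sp <- sparse_points(pts, center = c(12, 12), dim = c(26, 26))
  out <- close_active_contour(sp, "chan_vese", iterations = 0)
  hull <- segfuse:::fill_holes_px(oracle_chord_pixels(pts[1:4, ], c(26, 26)))
  expect_gte(oracle_jaccard(segfuse:::fill_holes_px(out$px), hull), 0.98)
})

test_that("collinear points never yield a non-closed active-contour output", {
  pts <- rbind(c(5, 5), c(10, 10), c(15, 15))
  expect_error(
    close_active_contour(sparse_points(pts, dim = c(20, 20)), "geodesic"),
    class = "segfuse_degenerate_error"
  )
})
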