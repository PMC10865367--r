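# Fixture builders and independent oracles shared across test files.
# Oracles are deliberately written as naive loops / set arithmetic, separate
# from the package's vectorized implementations.

disk_px <- function(h, w, cr, cc, r) {
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  (rows - cr)^2 + (cols - cc)^2 <= r^2
}

square_px <- function(h, w, r1, r2, c1, c2) {
  px <- matrix(FALSE, h, w)
  px[r1:r2, c1:c2] <- TRUE
  px
}

# square annulus: filled square minus a smaller concentric filled square
square_ring_px <- function(h, w, r1, r2, c1, c2, thick = 1L) {
  px <- square_px(h, w, r1, r2, c1, c2)
  px[(r1 + thick):(r2 - thick), (c1 + thick):(c2 - thick)] <- FALSE
  px
}

# brute-force internal boundary: per-pixel loop over the 4-neighbourhood
oracle_internal_boundary <- function(px) {
  h <- nrow(px); w <- ncol(px)
  out <- matrix(FALSE, h, w)
  for (r in seq_len(h)) for (c in seq_len(w)) {
    if (!px[r, c]) next
    nb <- c(
      if (r > 1) px[r - 1, c] else FALSE,
      if (r < h) px[r + 1, c] else FALSE,
      if (c > 1) px[r, c - 1] else FALSE,
      if (c < w) px[r, c + 1] else FALSE
    )
    if (!all(nb)) out[r, c] <- TRUE
  }
  out
}

# brute-force set-cardinality Jaccard on hole-filled masks
oracle_jaccard <- function(a, b) {
  ia <- which(as.vector(segfuse:::fill_holes_px(a)))
  ib <- which(as.vector(segfuse:::fill_holes_px(b)))
  length(intersect(ia, ib)) / length(union(ia, ib))
}

# random single-object blobby mask (threshold of a smoothed noise disk)
random_mask_px <- function(h, w, seed) {
  withr::with_seed(seed, {
    cr <- runif(1, h * 0.3, h * 0.7)
    cc <- runif(1, w * 0.3, w * 0.7)
    r <- runif(1, min(h, w) * 0.12, min(h, w) * 0.3)
    disk_px(h, w, cr, cc, r)
  })
}

# random star-shaped sparse point set about a centre
random_star_points <- function(seed, k_min = 8, k_max = 20,
                               r_min = 5, r_max = 22, center = c(28, 28)) {
  withr::with_seed(seed, {
    repeat {
      k <- sample(k_min:k_max, 1)
      theta <- sort(runif(k, 0, 2 * pi))
      r <- runif(k, r_min, r_max)
      pts <- cbind(round(center[1] - r * sin(theta)),
                   round(center[2] + r * cos(theta)))
      pts <- unique(pts)
      if (nrow(pts) >= 3) return(pts)
    }
  })
}

# independent chord rasterizer: dense parametric sampling + rounding
oracle_chord_pixels <- function(verts, dim) {
  verts <- rbind(verts, verts[1, , drop = FALSE])
  px <- matrix(FALSE, dim[1], dim[2])
  for (i in seq_len(nrow(verts) - 1)) {
    a <- verts[i, ]; b <- verts[i + 1, ]
    n <- max(2, ceiling(4 * max(abs(b - a))))
    t <- seq(0, 1, length.out = n)
    pr <- round(a[1] + t * (b[1] - a[1]))
    pc <- round(a[2] + t * (b[2] - a[2]))
    ok <- pr >= 1 & pr <= dim[1] & pc >= 1 & pc <= dim[2]
    px[cbind(pr[ok], pc[ok])] <- TRUE
  }
  px
}

boundary_set <- function(truth, n = 5, amplitude = 2, seed = 0) {
  specs <- lapply(seq_len(n), function(i) {
    rater_spec("boundary", amplitude = amplitude, seed = seed * 100 + i)
  })
  simulate_raters(truth, specs)
}

# independent, deliberately plain binary-STAPLE EM used as a cross-check
oracle_staple_em <- function(masks, n_iter = 1000) {
  D <- vapply(masks, as.vector, logical(length(masks[[1]])))
  prior <- mean(D)
  ref <- rowMeans(D) >= 0.5
  p <- pmax(pmin(colSums(D & ref) / sum(ref), 1 - 1e-6), 1e-6)
  q <- pmax(pmin(colSums(!D & !ref) / sum(!ref), 1 - 1e-6), 1e-6)
  w <- as.numeric(ref)
  for (it in seq_len(n_iter)) {
    a <- rep(log(prior), nrow(D))
    b <- rep(log(1 - prior), nrow(D))
    for (j in seq_len(ncol(D))) {
      a <- a + ifelse(D[, j], log(p[j]), log(1 - p[j]))
      b <- b + ifelse(D[, j], log(1 - q[j]), log(q[j]))
    }
    w_new <- 1 / (1 + exp(b - a))
    if (max(abs(w_new - w)) < 1e-10) { w <- w_new; break }
    w <- w_new
    p <- pmax(pmin(colSums(D * w) / sum(w), 1 - 1e-6), 1e-6)
    q <- pmax(pmin(colSums((1 - D) * (1 - w)) / sum(1 - w), 1 - 1e-6), 1e-6)
  }
  list(w = w, p = as.numeric(p), q = as.numeric(q))
}
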