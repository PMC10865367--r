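# Morphological active contours (Marquez-Neila, Baumela & Alvarez, IEEE TPAMI
# 2014): the PDE-based Chan-Vese and geodesic active-contour evolutions are
# approximated by compositions of binary morphological operators on the
# level-set indicator, which keeps the whole scheme integer-stable and fast.

# Curvature smoothing: SI(u) = sup over 3-pixel line segments of the erosion,
# IS(u) = inf over the dilations; one smoothing pass is ISoSI or SIoIS,
# alternating between calls.
.snake_lines <- list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))

sup_inf <- function(u) {
  Reduce(`|`, lapply(.snake_lines, function(o) {
    u & nbr_mat(u, o[1], o[2]) & nbr_mat(u, -o[1], -o[2])
  }))
}

inf_sup <- function(u) {
  Reduce(`&`, lapply(.snake_lines, function(o) {
    u | nbr_mat(u, o[1], o[2]) | nbr_mat(u, -o[1], -o[2])
  }))
}

smooth_curvature <- function(u, passes, state) {
  for (i in seq_len(passes)) {
    u <- if (state$flip) inf_sup(sup_inf(u)) else sup_inf(inf_sup(u))
    state$flip <- !state$flip
  }
  u
}

grad_central <- function(m) {
  gr <- (nbr_mat(m, 1, 0, 0) - nbr_mat(m, -1, 0, 0)) / 2
  gc <- (nbr_mat(m, 0, 1, 0) - nbr_mat(m, 0, -1, 0)) / 2
  list(r = gr, c = gc)
}

# Morphological Chan-Vese (ACWE): image attachment flips boundary-band pixels
# toward the region whose mean they resemble, then curvature smoothing.
morph_acwe <- function(image, init, iterations = 100L, smoothing = 1L,
                       lambda1 = 1, lambda2 = 1) {
  u <- init
  state <- new.env()
  state$flip <- TRUE
  for (it in seq_len(iterations)) {
    inside <- u
    if (!any(inside) || all(inside)) break
    c1 <- mean(image[inside])
    c0 <- mean(image[!inside])
    un <- matrix(as.numeric(u), nrow(u))
    g <- grad_central(un)
    band <- (abs(g$r) + abs(g$c)) > 0
    aux <- lambda1 * (image - c1)^2 - lambda2 * (image - c0)^2
    u[band & aux < 0] <- TRUE
    u[band & aux > 0] <- FALSE
    u <- smooth_curvature(u, smoothing, state)
  }
  u
}

# Morphological GAC: balloon force (erosion for a shrinking contour) applied
# where the stopping function g is above threshold (g is ~1 far from edges
# and ~0 on them), then advection along the gradient of g, then curvature
# smoothing.
morph_gac <- function(g, init, iterations = 100L, smoothing = 1L,
                      balloon = -1, threshold = 0.3) {
  u <- init
  dg <- grad_central(g)
  if (balloon != 0) mask_balloon <- g > threshold / abs(balloon)
  state <- new.env()
  state$flip <- TRUE
  for (it in seq_len(iterations)) {
    if (!any(u)) break
    if (balloon > 0) {
      aux <- dilate_sq(u, 1L)
      u[mask_balloon] <- aux[mask_balloon]
    } else if (balloon < 0) {
      aux <- erode_sq(u, 1L)
      u[mask_balloon] <- aux[mask_balloon]
    }
    un <- matrix(as.numeric(u), nrow(u))
    du <- grad_central(un)
    adv <- dg$r * du$r + dg$c * du$c
    u[adv > 0] <- TRUE
    u[adv < 0] <- FALSE
    u <- smooth_curvature(u, smoothing, state)
  }
  u
}
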