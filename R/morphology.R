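# Low-level binary morphology on plain logical matrices.
#
# Conventions used throughout the package:
#   * matrices are indexed [row, col], 1-based, row 1 at the top of the image;
#   * foreground is 8-connected, background is 4-connected (the standard dual
#     pair: it prevents a diagonal 1-pixel line from "leaking" background
#     through it while still letting diagonal contour steps count as closed);
#   * pixels outside the canvas are background.

shift_mat <- function(m, dr, dc, fill = FALSE) {
  h <- nrow(m)
  w <- ncol(m)
  out <- matrix(fill, h, w)
  r1 <- max(1L, 1L + dr)
  r2 <- min(h, h + dr)
  c1 <- max(1L, 1L + dc)
  c2 <- min(w, w + dc)
  if (r1 > r2 || c1 > c2) return(out)
  out[r1:r2, c1:c2] <- m[(r1 - dr):(r2 - dr), (c1 - dc):(c2 - dc)]
  out
}

# neighbour value matrices: out[r, c] = m[r + dr, c + dc]
nbr_mat <- function(m, dr, dc, fill = FALSE) shift_mat(m, -dr, -dc, fill)

.OFFS4 <- list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
.OFFS8 <- list(c(-1L, 0L), c(-1L, 1L), c(0L, 1L), c(1L, 1L),
               c(1L, 0L), c(1L, -1L), c(0L, -1L), c(-1L, -1L))

neighbor_count8 <- function(px) {
  Reduce(`+`, lapply(.OFFS8, function(o) nbr_mat(px, o[1], o[2])))
}

dilate4 <- function(px) {
  px | nbr_mat(px, -1, 0) | nbr_mat(px, 1, 0) | nbr_mat(px, 0, -1) | nbr_mat(px, 0, 1)
}

dilate_sq <- function(px, k = 1L) {
  for (i in seq_len(k)) {
    px <- Reduce(`|`, lapply(.OFFS8, function(o) nbr_mat(px, o[1], o[2])), px)
  }
  px
}

erode_sq <- function(px, k = 1L) {
  for (i in seq_len(k)) {
    px <- Reduce(`&`, lapply(.OFFS8, function(o) nbr_mat(px, o[1], o[2])), px)
  }
  px
}

# Connected-component labelling. EBImage::bwlabel labels 4-connected sets;
# 8-connectivity is obtained by merging labels that touch diagonally.
label_components <- function(px, conn = 8) {
  lab <- EBImage::bwlabel(matrix(as.numeric(px), nrow(px)))
  lab <- matrix(as.integer(round(lab)), nrow(px))
  nmax <- max(lab)
  if (conn == 8 && nmax > 1L) {
    parent <- seq_len(nmax)
    find <- function(i) {
      while (parent[i] != i) {
        parent[i] <<- parent[parent[i]]
        i <- parent[i]
      }
      i
    }
    for (off in list(c(1L, 1L), c(1L, -1L))) {
      sh <- nbr_mat(lab, off[1], off[2], fill = 0L)
      sel <- lab > 0L & sh > 0L & lab != sh
      if (any(sel)) {
        prs <- unique(cbind(lab[sel], sh[sel]))
        for (k in seq_len(nrow(prs))) {
          a <- find(prs[k, 1])
          b <- find(prs[k, 2])
          if (a != b) parent[b] <- a
        }
      }
    }
    root <- vapply(seq_len(nmax), find, integer(1))
    remap <- integer(nmax)
    u <- sort(unique(root))
    remap[u] <- seq_along(u)
    sel <- lab > 0L
    lab[sel] <- remap[root[lab[sel]]]
  }
  lab
}

n_components <- function(px, conn = 8) {
  if (!any(px)) return(0L)
  max(label_components(px, conn))
}

largest_component <- function(px, conn = 8) {
  if (!any(px)) return(px)
  lab <- label_components(px, conn)
  tab <- tabulate(lab[lab > 0L])
  lab == which.max(tab)
}

# Background pixels not 4-connected to the image border become foreground.
fill_holes_px <- function(px) {
  if (all(px)) return(px)
  bg <- !px
  lab <- matrix(
    as.integer(round(EBImage::bwlabel(matrix(as.numeric(bg), nrow(bg))))),
    nrow(bg)
  )
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  border <- border[border > 0L]
  holes <- bg & !matrix(lab %in% border, nrow(lab))
  px | holes
}

# Foreground pixels with at least one 4-neighbour in the background
# (pixels outside the canvas count as background).
internal_boundary_px <- function(px) {
  px & !(nbr_mat(px, -1, 0) & nbr_mat(px, 1, 0) &
           nbr_mat(px, 0, -1) & nbr_mat(px, 0, 1))
}

# Background pixels 4-adjacent to the foreground.
external_boundary_px <- function(px) {
  dilate4(px) & !px
}

is_closed_px <- function(px) {
  any(fill_holes_px(px) & !px)
}

# Zhang-Suen topology-preserving thinning. Pixels in `protect` are never
# removed (used to honour the all-input-pixels-preserved guarantee of the
# interpolation closers). A 1-pixel-wide closed loop is a fixed point: every
# pixel on it has two or more crossing-number transitions, so the A == 1
# deletion condition never fires.
thin_zs <- function(px, protect = NULL) {
  if (!any(px)) return(px)
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      n <- lapply(.OFFS8, function(o) nbr_mat(px, o[1], o[2]))
      # n[[1]]..n[[8]] are P2..P9 (N, NE, E, SE, S, SW, W, NW)
      B <- Reduce(`+`, n)
      sq <- c(n, n[1])
      A <- Reduce(`+`, lapply(1:8, function(i) (!sq[[i]]) & sq[[i + 1]]))
      if (step == 1) {
        cond <- px & B >= 2 & B <= 6 & A == 1 &
          !(n[[1]] & n[[3]] & n[[5]]) & !(n[[3]] & n[[5]] & n[[7]])
      } else {
        cond <- px & B >= 2 & B <= 6 & A == 1 &
          !(n[[1]] & n[[3]] & n[[7]]) & !(n[[1]] & n[[5]] & n[[7]])
      }
      if (!is.null(protect)) cond <- cond & !protect
      if (any(cond)) {
        px <- px & !cond
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  px
}

# Iteratively delete endpoint pixels (<= 1 neighbour of the 8) until none
# remain; on a skeleton this erases open spurs and keeps only closed loops.
prune_spurs_px <- function(px) {
  repeat {
    ep <- px & neighbor_count8(px) <= 1
    if (!any(ep)) return(px)
    px <- px & !ep
  }
}

# Euclidean distance from every pixel to the nearest TRUE pixel of `px`.
dist_to_px <- function(px) {
  if (!any(px)) sf_abort("distance transform of an empty pixel set", "segfuse_degenerate_error")
  d <- EBImage::distmap(matrix(as.numeric(!px), nrow(px)))
  matrix(as.numeric(d), nrow(px))
}

# Integer Bresenham segment between two pixels (inclusive); returns an
# n x 2 matrix of (row, col).
bresenham <- function(r0, c0, r1, c1) {
  dr <- abs(r1 - r0)
  dc <- abs(c1 - c0)
  sr <- if (r0 < r1) 1L else -1L
  sc <- if (c0 < c1) 1L else -1L
  err <- dc - dr
  n <- max(dr, dc) + 1L
  out <- matrix(0L, n, 2)
  r <- r0
  cc <- c0
  for (i in seq_len(n)) {
    out[i, ] <- c(r, cc)
    if (r == r1 && cc == c1) break
    e2 <- 2L * err
    if (e2 > -dr) {
      err <- err - dr
      cc <- cc + sc
    }
    if (e2 < dc) {
      err <- err + dc
      r <- r + sr
    }
  }
  out[seq_len(i), , drop = FALSE]
}

# Rasterize a closed polyline given as an n x 2 matrix of continuous (row, col)
# vertices onto an H x W canvas.
rasterize_closed_path <- function(verts, dim, closed = TRUE) {
  v <- round(verts)
  if (closed) v <- rbind(v, v[1, , drop = FALSE])
  px <- matrix(FALSE, dim[1], dim[2])
  for (i in seq_len(nrow(v) - 1L)) {
    seg <- bresenham(v[i, 1], v[i, 2], v[i + 1, 1], v[i + 1, 2])
    keep <- seg[, 1] >= 1 & seg[, 1] <= dim[1] & seg[, 2] >= 1 & seg[, 2] <= dim[2]
    if (any(keep)) px[seg[keep, , drop = FALSE]] <- TRUE
  }
  px
}
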