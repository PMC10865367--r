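# The eight fusion algorithms. Every algorithm consumes a segmentation_set
# whose masks have been pre-processed to one-pixel contour lines (per the
# configured line-extraction mode) together with their filled regions, and
# emits a closed one-pixel contour_line.

#' Fusion configuration
#'
#' Collects the algorithm choice and all advanced options in one object. The
#' defaults (external one-pixel line, shape-preserving closing) match the
#' tool's default configuration.
#'
#' @param algorithm One of `"largest"`, `"smallest"`, `"avg_smallest_largest"`,
#'   `"avg_target_largest"`, `"avg_target_smallest"`, `"avg_target_input"`,
#'   `"middle"`, `"staple"`, or the name of a registered plugin.
#' @param line_mode Line-extraction mode for the inputs and the output
#'   perimeter: `"external"` (default), `"internal"` or `"middle"`.
#' @param closing Closing method for sparse consensus points: `"pchip"`
#'   (shape-preserving, default), `"linear"`, `"chan_vese"` or `"geodesic"`.
#' @param middle_tiebreak Sub-algorithm fusing the two survivors of Middle
#'   when N is even: `"average"` (default; Average Smallest And Largest),
#'   `"largest"` or `"smallest"`.
#' @param target_index 1-based rater index of the target segmentation
#'   (required for `avg_target_input` only).
#' @param staple_max_iter,staple_tol,staple_threshold STAPLE EM controls; see
#'   [staple_consensus()].
#' @param extra Named list of extra parameters for plugin algorithms,
#'   validated against the plugin's declared schema.
#' @return An object of class `fusion_config`.
#' @export
fusion_config <- function(algorithm = "middle",
                          line_mode = c("external", "internal", "middle"),
                          closing = c("pchip", "linear", "chan_vese", "geodesic"),
                          middle_tiebreak = c("average", "largest", "smallest"),
                          target_index = NULL,
                          staple_max_iter = 100L,
                          staple_tol = 1e-6,
                          staple_threshold = 0.5,
                          extra = list()) {
  line_mode <- match.arg(line_mode)
  closing <- match.arg(closing)
  middle_tiebreak <- match.arg(middle_tiebreak)
  if (!is.null(target_index)) {
    target_index <- as.integer(target_index)
    if (is.na(target_index) || target_index < 1L) {
      sf_abort("target_index must be a positive integer", "segfuse_config_error")
    }
  }
  if (staple_max_iter < 1) sf_abort("staple_max_iter must be positive", "segfuse_config_error")
  if (staple_tol <= 0) sf_abort("staple_tol must be positive", "segfuse_config_error")
  if (staple_threshold <= 0 || staple_threshold >= 1) {
    sf_abort("staple_threshold must lie in (0, 1)", "segfuse_config_error")
  }
  structure(list(algorithm = algorithm, line_mode = line_mode, closing = closing,
                 middle_tiebreak = middle_tiebreak, target_index = target_index,
                 staple_max_iter = as.integer(staple_max_iter),
                 staple_tol = staple_tol, staple_threshold = staple_threshold,
                 extra = extra),
            class = "fusion_config")
}

perimeter_side <- function(line_mode) {
  # "middle" is undefined for a filled fused region; its perimeter degrades
  # to the internal boundary
  if (line_mode == "middle") "internal" else line_mode
}

# Pre-process a set: one-pixel contour line and filled region per input.
prep_set <- function(set, line_mode) {
  lines <- lapply(set$masks, extract_line, mode = line_mode)
  regions <- lapply(lines, function(l) fill_holes_px(l$px))
  list(lines = lines, regions = regions,
       dim = dim(set$masks[[1]]$px), n = set$n)
}

union_region <- function(regions) Reduce(`|`, regions)
intersect_region <- function(regions) Reduce(`&`, regions)

set_center <- function(prep) {
  u <- fill_holes_px(union_region(prep$regions))
  idx <- which(u, arr.ind = TRUE)
  colMeans(idx)
}

#' Fuse a segmentation set into a consensus contour
#'
#' Dispatches to the configured fusion algorithm (built-in or registered
#' plugin). Inputs are first reduced to one-pixel contour lines according to
#' `config$line_mode`; the output is always a closed one-pixel `contour_line`.
#'
#' @param set A [segmentation_set].
#' @param config A [fusion_config].
#' @return A `contour_line`.
#' @examples
#' inner <- matrix(FALSE, 16, 16); inner[6:10, 6:10] <- TRUE
#' outer <- matrix(FALSE, 16, 16); outer[4:12, 4:12] <- TRUE
#' set <- segmentation_set(list(binary_mask(inner), binary_mask(outer)))
#' out <- fuse(set, fusion_config("largest", line_mode = "internal"))
#' sum(out$px)  # perimeter of the 9x9 square: 32 pixels
#' @export
fuse <- function(set, config = fusion_config()) {
  if (!inherits(set, "segmentation_set")) {
    sf_abort("fuse() expects a segmentation_set", "segfuse_format_error")
  }
  if (!inherits(config, "fusion_config")) {
    sf_abort("fuse() expects a fusion_config", "segfuse_config_error")
  }
  entry <- registry_get(config$algorithm)
  if (is.null(entry)) {
    sf_abort(sprintf("unknown fusion algorithm '%s'; registered algorithms: %s",
                     config$algorithm,
                     paste(list_algorithms(), collapse = ", ")),
             "segfuse_config_error")
  }
  if (identical(config$algorithm, "avg_target_input")) {
    if (is.null(config$target_index)) {
      sf_abort("avg_target_input requires target_index", "segfuse_config_error")
    }
    if (config$target_index > set$n) {
      sf_abort(sprintf("target_index %d exceeds the number of segmentations (%d)",
                       config$target_index, set$n), "segfuse_config_error")
    }
  }
  if (length(entry$params_schema)) {
    config$extra <- validate_params(entry$params_schema, config$extra,
                                    config$algorithm)
  }
  entry$fn(set, config)
}

# ---- Largest / Smallest ----------------------------------------------------

fuse_largest_impl <- function(set, config) {
  prep <- prep_set(set, config$line_mode)
  u <- fill_holes_px(union_region(prep$regions))
  if (n_components(u, 8) > 1L) {
    sf_abort("union of the segmentations is disconnected; the tool fuses one object",
             "segfuse_multi_object_error")
  }
  region_perimeter(new_region_mask(u), side = perimeter_side(config$line_mode))
}

fuse_smallest_impl <- function(set, config) {
  prep <- prep_set(set, config$line_mode)
  counts <- Reduce(`+`, lapply(prep$regions, function(r) matrix(as.integer(r), nrow(r))))
  common <- counts == prep$n
  if (!any(common)) {
    sf_abort("the segmentations share no common area (empty intersection)",
             "segfuse_empty_intersection_error")
  }
  if (n_components(common, 8) > 1L) {
    sf_abort("the common area is disconnected; the tool fuses one object",
             "segfuse_multi_object_error")
  }
  region_perimeter(new_region_mask(common), side = perimeter_side(config$line_mode))
}

# ---- Average Smallest And Largest ------------------------------------------

# The middle line between Smallest and Largest: skeletonize the closed band
# between the two regions (the annulus plus both boundary rings) and prune it
# to a single closed loop.
fuse_avg_smallest_largest_impl <- function(set, config) {
  prep <- prep_set(set, config$line_mode)
  L <- fill_holes_px(union_region(prep$regions))
  counts <- Reduce(`+`, lapply(prep$regions, function(r) matrix(as.integer(r), nrow(r))))
  S <- counts == prep$n
  if (!any(S)) {
    sf_abort("the segmentations share no common area (empty intersection)",
             "segfuse_empty_intersection_error")
  }
  if (identical(L, S)) {
    return(region_perimeter(new_region_mask(L), side = perimeter_side(config$line_mode)))
  }
  # skeleton of the closed band between the two regions = the equidistant
  # (distance-transform) midline; iterative thinning is not used here because
  # the band's convex outer boundary thins faster than its concave inner one,
  # which would bias the line inward
  d_in <- dist_to_px(S)
  d_out <- dist_to_px(!L)
  mid_region <- S | (L & d_in <= d_out)
  sk <- internal_boundary_px(mid_region)
  sk <- prune_spurs_px(thin_zs(sk))
  if (!any(sk) || !is_closed_px(sk)) {
    sf_abort("skeleton of the Smallest-to-Largest band is not a closed loop",
             "segfuse_topology_error")
  }
  new_contour_line(sk, "middle")
}

# ---- Average Target family -------------------------------------------------

#' Nearest contour pixel to a target pixel
#'
#' Returns the pixel of `other_contour` minimizing the Euclidean distance to
#' `target_pixel`. Ties are broken by the smallest row, then smallest column.
#'
#' @param target_pixel Numeric `c(row, col)`.
#' @param other_contour A `contour_line`, mask or logical matrix.
#' @return Integer `c(row, col)`.
#' @export
nearest_member <- function(target_pixel, other_contour) {
  px <- as_px(other_contour)
  idx <- which(px, arr.ind = TRUE)
  if (nrow(idx) == 0L) sf_abort("empty contour", "segfuse_empty_error")
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  d2 <- (idx[, 1] - target_pixel[1])^2 + (idx[, 2] - target_pixel[2])^2
  as.integer(idx[which.min(d2), ])
}

#' Consensus point of a pixel group
#'
#' Given the group formed by a target-contour pixel and the nearest pixel of
#' every other contour, computes the new consensus point: the midpoint for 2
#' points; the midpoint of the two mutually farthest points when all points
#' are exactly collinear (integer cross-product test); the arithmetic mean
#' (centroid) otherwise. The result is continuous; callers round it to the
#' pixel grid.
#'
#' @param members An m x 2 matrix of (row, col) pixel coordinates, m >= 2.
#' @return Numeric `c(row, col)`.
#' @examples
#' group_consensus(rbind(c(0, 0), c(2, 2)))           # c(1, 1)
#' group_consensus(rbind(c(0, 0), c(1, 1), c(4, 4)))  # c(2, 2)
#' @export
group_consensus <- function(members) {
  members <- as.matrix(members)
  m <- nrow(members)
  if (m < 2L) sf_abort("a pixel group needs at least 2 members", "segfuse_degenerate_error")
  if (m == 2L) return(colMeans(members))
  a <- members[1, ]
  b <- NULL
  for (i in 2:m) {
    if (any(members[i, ] != a)) { b <- members[i, ]; break }
  }
  if (is.null(b)) return(as.numeric(a))  # all identical
  cross <- (members[, 1] - a[1]) * (b[2] - a[2]) - (members[, 2] - a[2]) * (b[1] - a[1])
  if (all(cross == 0)) {
    d2 <- as.matrix(stats::dist(members))^2
    far <- which(d2 == max(d2), arr.ind = TRUE)[1, ]
    return((members[far[1], ] + members[far[2], ]) / 2)
  }
  colMeans(members)
}

fuse_avg_target_impl <- function(set, config, target) {
  prep <- prep_set(set, config$line_mode)
  side <- perimeter_side(config$line_mode)
  target_idx <- NULL
  target_line <- switch(target,
    largest = {
      u <- fill_holes_px(union_region(prep$regions))
      region_perimeter(new_region_mask(u), side = side)
    },
    smallest = {
      common <- intersect_region(prep$regions)
      if (!any(common)) {
        sf_abort("the segmentations share no common area (empty intersection)",
                 "segfuse_empty_intersection_error")
      }
      region_perimeter(new_region_mask(common), side = side)
    },
    input = {
      target_idx <- config$target_index
      prep$lines[[target_idx]]
    }
  )
  tpix <- which(target_line$px, arr.ind = TRUE)
  # one member per input segmentation: the target pixel stands in for the
  # target input itself (when the target is one of the inputs)
  others <- lapply(prep$lines, function(l) {
    idx <- which(l$px, arr.ind = TRUE)
    idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  })
  consensus <- matrix(0, nrow(tpix), 2)
  for (i in seq_len(nrow(tpix))) {
    tp <- tpix[i, ]
    members <- matrix(0, prep$n, 2)
    for (j in seq_len(prep$n)) {
      if (!is.null(target_idx) && j == target_idx) {
        members[j, ] <- tp
      } else {
        idx <- others[[j]]
        d2 <- (idx[, 1] - tp[1])^2 + (idx[, 2] - tp[2])^2
        members[j, ] <- idx[which.min(d2), ]
      }
    }
    consensus[i, ] <- group_consensus(members)
  }
  pts <- unique(round_half_away(consensus))
  if (nrow(pts) < 3L) {
    sf_abort("fewer than 3 distinct consensus pixels; cannot form a closed line",
             "segfuse_degenerate_error")
  }
  sp <- sparse_points(pts, center = set_center(prep), dim = prep$dim)
  close_with(sp, config)
}

round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

close_with <- function(sp, config) {
  switch(config$closing,
    linear = close_linear(sp),
    pchip = close_pchip(sp),
    chan_vese = close_active_contour(sp, "chan_vese"),
    geodesic = close_active_contour(sp, "geodesic")
  )
}

# ---- Middle ----------------------------------------------------------------

fuse_middle_impl <- function(set, config) {
  prep <- prep_set(set, config$line_mode)
  areas <- vapply(prep$regions, sum, numeric(1))
  alive <- seq_len(prep$n)
  n_iter <- (prep$n - 1L) %/% 2L
  for (it in seq_len(n_iter)) {
    # ties: the candidate with the lowest rater index is removed
    i_min <- alive[which.min(areas[alive])]
    alive <- setdiff(alive, i_min)
    i_max <- alive[which.max(areas[alive])]
    alive <- setdiff(alive, i_max)
  }
  out <- if (length(alive) == 1L) {
    prep$lines[[alive]]
  } else {
    sub <- segmentation_set(set$masks[alive])
    sub_alg <- switch(config$middle_tiebreak,
                      average = fuse_avg_smallest_largest_impl,
                      largest = fuse_largest_impl,
                      smallest = fuse_smallest_impl)
    sub_alg(sub, config)
  }
  attr(out, "middle_iterations") <- n_iter
  attr(out, "middle_survivors") <- alive
  out
}

# ---- STAPLE ----------------------------------------------------------------

fuse_staple_impl <- function(set, config) {
  prep <- prep_set(set, config$line_mode)
  fit <- staple_consensus(prep$regions,
                          max_iter = config$staple_max_iter,
                          tol = config$staple_tol,
                          threshold = config$staple_threshold)
  region <- fit$region
  if (!any(region) || all(region)) {
    sf_abort("STAPLE consensus is degenerate (all-foreground or all-background)",
             "segfuse_degenerate_vote_error")
  }
  region <- fill_holes_px(region)
  if (n_components(region, 8) > 1L) {
    sf_warn("STAPLE consensus split into several components; keeping the largest",
            "segfuse_component_warning")
    region <- largest_component(region)
  }
  out <- region_perimeter(new_region_mask(region),
                          side = perimeter_side(config$line_mode))
  attr(out, "staple") <- fit[c("performance", "prior", "iterations", "converged")]
  out
}
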