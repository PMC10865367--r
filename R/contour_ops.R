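#' Fill enclosed holes in a mask
#'
#' Background pixels that are not 4-connected to the image border become
#' foreground, turning a drawn closed line (possibly thicker than one pixel)
#' into the filled region it encloses. Idempotent.
#'
#' @param mask A [binary_mask] or logical matrix.
#' @return A `region_mask` (subclass of [binary_mask]).
#' @examples
#' ring <- matrix(FALSE, 9, 9); ring[3:7, 3:7] <- TRUE; ring[4:6, 4:6] <- FALSE
#' sum(fill_holes(binary_mask(ring))$px)  # 25: the filled square
#' @export
fill_holes <- function(mask) {
  px <- as_px(mask)
  new_region_mask(fill_holes_px(px),
                  source = if (inherits(mask, "binary_mask")) mask$source else NULL)
}

#' Extract a closed one-pixel contour line from a mask
#'
#' Three modes, matching how a drawn boundary thicker than one pixel can be
#' reduced to a one-pixel line:
#' * `internal`: foreground pixels of the hole-filled mask that touch the
#'   background with a 4-neighbour;
#' * `external`: background pixels 4-adjacent to the hole-filled mask;
#' * `middle`: the 1-pixel skeleton (topology-preserving thinning followed by
#'   spur pruning) of the original, unfilled thick line.
#'
#' `middle` is only meaningful when the input actually is a thick closed line
#' (an annulus); on a filled blob it falls back to `internal` with a warning.
#'
#' @param mask A [binary_mask] or logical matrix.
#' @param mode One of `"internal"`, `"middle"`, `"external"`.
#' @return A `contour_line`.
#' @export
extract_line <- function(mask, mode = c("external", "internal", "middle")) {
  mode <- match.arg(mode)
  px <- as_px(mask)
  src <- if (inherits(mask, "binary_mask")) mask$source else NULL
  filled <- fill_holes_px(px)
  if (mode == "middle") {
    if (sum(filled) > sum(px)) {      # the line encloses background: annulus
      sk <- prune_spurs_px(thin_zs(px))
      if (!any(sk) || !is_closed_px(sk)) {
        sf_abort("skeleton of the thick line cannot be pruned to a closed loop",
                 "segfuse_topology_error")
      }
      return(new_contour_line(sk, "middle", src))
    }
    sf_warn("middle line requested on a filled region with no annulus structure; using internal line",
            "segfuse_fallback_warning")
    mode <- "internal"
  }
  region_perimeter(new_region_mask(filled, src), side = mode)
}

#' One-pixel perimeter of a filled region
#'
#' @param region A `region_mask` (or any mask; holes are filled first).
#' @param side `"internal"` (boundary pixels inside the region) or
#'   `"external"` (ring of background pixels around it). An external ring
#'   cannot be drawn for a region touching the image border.
#' @return A `contour_line`.
#' @export
region_perimeter <- function(region, side = c("external", "internal")) {
  side <- match.arg(side)
  px <- fill_holes_px(as_px(region))
  src <- if (inherits(region, "binary_mask")) region$source else NULL
  if (side == "internal") {
    return(new_contour_line(internal_boundary_px(px), "internal", src))
  }
  touches <- any(px[1, ]) || any(px[nrow(px), ]) || any(px[, 1]) || any(px[, ncol(px)])
  if (touches) {
    sf_abort("region touches the image border: the external one-pixel ring would leave the canvas",
             "segfuse_border_error")
  }
  new_contour_line(external_boundary_px(px), "external", src)
}

#' Is a one-pixel line a closed loop?
#'
#' A line is closed when flood-filling the background from the image border
#' (4-connectivity) leaves at least one background pixel unreached, i.e. the
#' line encloses an interior.
#'
#' @param line A `contour_line`, [binary_mask] or logical matrix.
#' @return `TRUE` or `FALSE`.
#' @export
is_closed <- function(line) {
  is_closed_px(as_px(line))
}

#' Thin a pixel set to one-pixel width
#'
#' Topology-preserving (Zhang-Suen) thinning. A valid contour line is a fixed
#' point of this operation, which is how the one-pixel-wide invariant is
#' checked.
#'
#' @param mask A mask, contour or logical matrix.
#' @param prune Also prune open spurs (endpoint pixels) after thinning.
#' @return A logical matrix.
#' @export
thin_mask <- function(mask, prune = FALSE) {
  px <- thin_zs(as_px(mask))
  if (prune) px <- prune_spurs_px(px)
  px
}
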