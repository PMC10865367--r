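#' Jaccard index of two segmentations
#'
#' `JI(A, B) = |A intersect B| / |A union B|`. Both inputs are hole-filled
#' before counting, so one-pixel contour lines are compared as the regions
#' they enclose (the index of two thin rings as raw pixel sets would be close
#' to zero and meaningless for boundary agreement).
#'
#' @param a,b Masks, contour lines, or logical matrices of equal dimensions.
#' @return An object of class `jaccard_score` with fields `value`,
#'   `intersection_px` and `union_px`.
#' @examples
#' m <- matrix(FALSE, 8, 8); m[2:5, 2:5] <- TRUE
#' n <- matrix(FALSE, 8, 8); n[4:7, 4:7] <- TRUE
#' jaccard(m, n)$value  # 4 / 28
#' @export
jaccard <- function(a, b) {
  pa <- fill_holes_px(as_px(a))
  pb <- fill_holes_px(as_px(b))
  if (!identical(dim(pa), dim(pb))) {
    sf_abort(sprintf("dimension mismatch: %dx%d vs %dx%d",
                     nrow(pa), ncol(pa), nrow(pb), ncol(pb)),
             "segfuse_shape_error")
  }
  inter <- sum(pa & pb)
  uni <- sum(pa | pb)
  if (uni == 0L) {
    sf_abort("Jaccard index undefined: both masks are empty after hole filling",
             "segfuse_empty_error")
  }
  structure(list(value = inter / uni, intersection_px = inter, union_px = uni),
            class = "jaccard_score")
}

#' @export
print.jaccard_score <- function(x, ...) {
  cat(sprintf("JI = %.4f (%d / %d px)\n", x$value, x$intersection_px, x$union_px))
  invisible(x)
}

#' Rank fusion configurations by mean Jaccard index
#'
#' Runs every configuration on every test case, scores each fused contour
#' against the case's ground truth with [jaccard()], and ranks the
#' configurations by descending mean JI (the layout of a benchmark table:
#' one row per algorithm, one JI column per case, then the mean and the
#' rank). A fusion failure leaves the cell `NA` with a warning; missing
#' cells are excluded from that row's mean rather than counted as zero.
#'
#' @param cases List of cases, each a list with elements `set` (a
#'   [segmentation_set]) and `truth` (a mask).
#' @param configs List of [fusion_config] objects.
#' @param labels Optional row labels; defaults to the algorithm names.
#' @return A `data.frame` with columns `algorithm`, one `case_<i>` per case,
#'   `mean` and `rank` (1-based, ties keep input order).
#' @export
rank_algorithms <- function(cases, configs, labels = NULL) {
  if (length(cases) < 1L) sf_abort("need at least one case", "segfuse_arity_error")
  if (length(configs) < 1L) sf_abort("need at least one config", "segfuse_arity_error")
  if (is.null(labels)) {
    labels <- vapply(configs, function(cf) {
      if (cf$algorithm == "middle") paste0("middle-", cf$middle_tiebreak)
      else if (cf$algorithm == "avg_target_input") {
        paste0("avg_target_input:", cf$target_index)
      } else cf$algorithm
    }, character(1))
  }
  ji <- matrix(NA_real_, length(configs), length(cases))
  for (ci in seq_along(cases)) {
    for (ai in seq_along(configs)) {
      ji[ai, ci] <- tryCatch(
        jaccard(fuse(cases[[ci]]$set, configs[[ai]]), cases[[ci]]$truth)$value,
        error = function(e) {
          sf_warn(sprintf("'%s' failed on case %d: %s", labels[ai], ci,
                          conditionMessage(e)), "segfuse_cell_warning")
          NA_real_
        })
    }
  }
  means <- rowMeans(ji, na.rm = TRUE)
  means[is.nan(means)] <- NA_real_
  ord <- order(-means, na.last = TRUE)
  rank <- integer(length(configs))
  rank[ord] <- seq_along(ord)
  out <- data.frame(algorithm = labels, stringsAsFactors = FALSE)
  for (ci in seq_along(cases)) out[[paste0("case_", ci)]] <- ji[, ci]
  out$mean <- means
  out$rank <- rank
  out
}
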