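#' Binary STAPLE expectation-maximization consensus
#'
#' Simultaneous Truth and Performance Level Estimation for binary masks.
#' Starting from a per-pixel majority vote, the EM loop alternates between
#' estimating each rater's sensitivity `p_j` (true-positive rate on the
#' hidden truth) and specificity `q_j` (true-negative rate), and recomputing
#' the per-pixel posterior foreground probability `W_i` from those estimates
#' and a fixed foreground prior. Votes of accurate raters thereby weigh more
#' than votes of sloppy ones.
#'
#' This is the estimation core and accepts arbitrary binary matrices (no
#' single-object requirement), so it can be run directly on raw rater fields;
#' [fuse()] with `algorithm = "staple"` wraps it with hole filling and
#' perimeter extraction.
#'
#' @param masks A [segmentation_set], or a list of logical matrices of equal
#'   dimensions (at least 2).
#' @param max_iter Maximum EM iterations (default 100).
#' @param tol Convergence tolerance on `max |W - W_prev|` (default 1e-6).
#' @param threshold Posterior threshold defining the consensus foreground
#'   (default 0.5).
#' @param prior Foreground prior probability; default is the mean foreground
#'   fraction across the input masks, held fixed over the iterations.
#' @return A list of class `staple_fit`: `w` (posterior matrix), `region`
#'   (logical consensus `W >= threshold`), `performance` (data frame with
#'   `sensitivity` and `specificity` per rater), `prior`, `iterations`,
#'   `converged`.
#' @references Warfield, Zou & Wells (2004) IEEE TMI 23(7), 903-921.
#' @export
staple_consensus <- function(masks, max_iter = 100L, tol = 1e-6,
                             threshold = 0.5, prior = NULL) {
  if (inherits(masks, "segmentation_set")) masks <- lapply(masks$masks, as_px)
  masks <- lapply(masks, as_px)
  if (length(masks) < 2L) {
    sf_abort("STAPLE needs at least 2 segmentations", "segfuse_arity_error")
  }
  dm <- dim(masks[[1]])
  if (!all(vapply(masks, function(m) identical(dim(m), dm), logical(1)))) {
    sf_abort("STAPLE inputs must share identical dimensions", "segfuse_shape_error")
  }
  D <- vapply(masks, as.vector, logical(length(masks[[1]])))
  n_rater <- ncol(D)
  if (is.null(prior)) prior <- mean(D)
  eps <- 1e-6

  ref <- rowMeans(D) >= 0.5
  if (all(ref) || !any(ref)) {
    sf_abort("degenerate majority vote: reference segmentation is all-foreground or all-background",
             "segfuse_degenerate_vote_error")
  }
  p <- pmin(pmax(colSums(D & ref) / sum(ref), eps), 1 - eps)
  q <- pmin(pmax(colSums(!D & !ref) / sum(!ref), eps), 1 - eps)

  w <- as.numeric(ref)
  ref_prev <- ref
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    # E-step: posterior log-odds of foreground at each pixel
    log_a <- log(prior) + D %*% log(p) + (1 - D) %*% log(1 - p)
    log_b <- log(1 - prior) + D %*% log(1 - q) + (1 - D) %*% log(q)
    w_new <- as.vector(1 / (1 + exp(log_b - log_a)))
    ref_new <- w_new >= threshold
    delta <- max(abs(w_new - w))
    w <- w_new
    # M-step
    sw <- sum(w)
    sv <- length(w) - sw
    p <- pmin(pmax(colSums(D * w) / sw, eps), 1 - eps)
    q <- pmin(pmax(colSums((1 - D) * (1 - w)) / sv, eps), 1 - eps)
    if (delta < tol || identical(ref_new, ref_prev)) {
      converged <- TRUE
      ref_prev <- ref_new
      break
    }
    ref_prev <- ref_new
  }
  if (!converged) {
    sf_warn(sprintf("STAPLE did not converge within %d iterations (last max |dW| above %g)",
                    max_iter, tol), "segfuse_convergence_warning")
  }
  structure(list(
    w = matrix(w, dm[1], dm[2]),
    region = matrix(w >= threshold, dm[1], dm[2]),
    performance = data.frame(rater = seq_len(n_rater),
                             sensitivity = as.numeric(p),
                             specificity = as.numeric(q)),
    prior = prior, iterations = it, converged = converged
  ), class = "staple_fit")
}

#' @export
print.staple_fit <- function(x, ...) {
  cat(sprintf("<staple_fit> %d iterations (%s), prior %.4f\n",
              x$iterations, if (x$converged) "converged" else "not converged",
              x$prior))
  print(x$performance, row.names = FALSE)
  invisible(x)
}
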