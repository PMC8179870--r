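# Binary STAPLE (Simultaneous Truth and Performance Level Estimation).
#
# EM alternates a voxelwise posterior over the hidden true segmentation
# (E-step) with per-rater sensitivity/specificity re-estimation (M-step).
# Voxels are compressed to unique rater-decision patterns (at most 2^J), so
# the EM cost is independent of volume size after the initial pass.

#' STAPLE consensus of multiple binary segmentations
#'
#' Estimates the hidden true segmentation and each rater's sensitivity
#' `p_j` and specificity `q_j` by expectation-maximisation. Computation is
#' restricted to the bounding box of the union of the masks dilated by
#' `margin` voxels; the posterior outside is 0. The foreground prior is
#' spatially constant: either a number in (0, 1) or `"sample-mean"` (the
#' mean foreground fraction over raters within the bounding box).
#'
#' @param masks list of >= 2 [label_volume()]s with identical geometry,
#'   each nonempty; names (or `rater_ids`) label the raters
#' @param prior `"sample-mean"` or a number in (0, 1)
#' @param tol convergence tolerance on the maximum absolute change of any
#'   `p_j`, `q_j` between iterations
#' @param max_iter maximum EM iterations; non-convergence returns
#'   `converged = FALSE` with a warning
#' @param threshold posterior level for the consensus mask; posterior
#'   exactly equal to the threshold counts as foreground
#' @param init initial value for all `p_j`, `q_j`
#' @param margin bounding-box dilation in voxels
#' @param rater_ids optional character vector of rater labels
#' @return object of class `staple_result`: `posterior` (3D array in
#'   `[0,1]`), `consensus` ([label_volume()]), `per_rater` (data.frame with
#'   `rater_id`, `sensitivity`, `specificity`), `n_iterations`,
#'   `converged`, `prior`
#' @examples
#' m <- label_volume(array(c(0, 1, 1, 0), c(4, 2, 2)), c(1, 1, 1))
#' res <- staple(list(a = m, b = m, c = m))
#' res$per_rater
#' @export
staple <- function(masks, prior = "sample-mean", tol = 1e-7, max_iter = 100L,
                   threshold = 0.5, init = 0.99999, margin = 10L,
                   rater_ids = NULL) {
  if (!is.list(masks) || length(masks) < 2)
    stop("staple needs a list of at least 2 masks", call. = FALSE)
  lapply(masks, function(m) stopifnot(is_label_volume(m)))
  for (m in masks[-1]) check_same_geometry(masks[[1]], m, "rater masks")
  if (all(vapply(masks, n_foreground, numeric(1)) == 0))
    stop("all rater masks are empty; consensus undefined", call. = FALSE)
  if (is.null(rater_ids))
    rater_ids <- names(masks) %||% sprintf("r%d", seq_along(masks))
  J <- length(masks)
  dims <- dim(masks[[1]]$voxels)

  # bounding box of the union, dilated
  un <- Reduce(`|`, lapply(masks, function(m) m$voxels == 1L))
  idx <- which(un, arr.ind = TRUE)
  lo <- pmax(apply(idx, 2, min) - margin, 1L)
  hi <- pmin(apply(idx, 2, max) + margin, dims)
  box <- list(lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3])

  D <- vapply(masks, function(m) {
    as.integer(m$voxels[box[[1]], box[[2]], box[[3]]])
  }, integer(prod(hi - lo + 1L)))
  # compress to unique decision patterns
  code <- as.vector(D %*% 2^(seq_len(J) - 1))
  tabs <- table(code)
  pat_code <- as.numeric(names(tabs))
  counts <- as.numeric(tabs)
  P <- t(vapply(pat_code, function(cd) as.integer((cd %/% 2^(seq_len(J) - 1)) %% 2),
                integer(J)))

  gamma <- if (identical(prior, "sample-mean")) mean(D) else {
    if (!is.numeric(prior) || prior <= 0 || prior >= 1)
      stop("prior must be 'sample-mean' or a number in (0, 1)", call. = FALSE)
    prior
  }

  clamp <- function(x) pmin(pmax(x, 1e-12), 1 - 1e-12)
  p <- rep(init, J); q <- rep(init, J)
  converged <- FALSE
  iter <- 0L
  W <- NULL
  while (iter < max_iter) {
    iter <- iter + 1L
    lp <- log(clamp(p)); l1p <- log1p(-clamp(p))
    lq <- log(clamp(q)); l1q <- log1p(-clamp(q))
    la <- log(gamma)     + as.vector(P %*% lp)  + as.vector((1 - P) %*% l1p)
    lb <- log1p(-gamma)  + as.vector(P %*% l1q) + as.vector((1 - P) %*% lq)
    m <- pmax(la, lb)
    W <- exp(la - m) / (exp(la - m) + exp(lb - m))
    cw <- counts * W
    sw <- sum(cw); sc <- sum(counts * (1 - W))
    p_new <- as.vector(crossprod(P, cw)) / sw
    q_new <- as.vector(crossprod(1 - P, counts * (1 - W))) / sc
    delta <- max(abs(c(p_new - p, q_new - q)))
    p <- p_new; q <- q_new
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning(sprintf("STAPLE did not converge in %d iterations", max_iter),
            call. = FALSE)

  post_box <- W[match(code, pat_code)]
  posterior <- array(0, dims)
  posterior[box[[1]], box[[2]], box[[3]]] <- post_box
  consensus <- label_volume(array(as.integer(posterior >= threshold), dims),
                            masks[[1]]$spacing)
  structure(list(posterior = posterior,
                 consensus = consensus,
                 per_rater = data.frame(rater_id = rater_ids,
                                        sensitivity = p, specificity = q,
                                        stringsAsFactors = FALSE),
                 n_iterations = iter, converged = converged, prior = gamma),
            class = "staple_result")
}

#' @export
print.staple_result <- function(x, ...) {
  cat(sprintf("<staple_result> %d raters, %d EM iterations (%s), prior %.4f, |consensus| = %d\n",
              nrow(x$per_rater), x$n_iterations,
              if (x$converged) "converged" else "NOT converged",
              x$prior, n_foreground(x$consensus)))
  print(x$per_rater)
  invisible(x)
}

#' Score one rater against the STAPLE consensus
#'
#' @param mask a rater's [label_volume()]
#' @param consensus a `staple_result` (or a [label_volume()] used directly
#'   as reference)
#' @param metric `"DSC"`, `"HD"` or `"AHD"`
#' @param units `"voxels"` or `"mm"` (distance metrics)
#' @param ... passed to [hausdorff()] / [average_hausdorff()]
#' @return the metric value
#' @export
compare_to_consensus <- function(mask, consensus,
                                 metric = c("DSC", "HD", "AHD"),
                                 units = c("voxels", "mm"), ...) {
  metric <- match.arg(metric); units <- match.arg(units)
  ref <- if (inherits(consensus, "staple_result")) consensus$consensus
         else consensus
  stopifnot(is_label_volume(ref))
  switch(metric,
         DSC = dice(mask, ref),
         HD = hausdorff(mask, ref, units, ...),
         AHD = average_hausdorff(mask, ref, units, ...))
}
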