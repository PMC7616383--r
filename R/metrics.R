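#' Structural similarity index (SSIM)
#'
#' Windowed luminance/contrast/structure similarity between an image and a
#' reference, averaged over all fully-interior windows. Uses a uniform
#' 7 x 7 window, the conventional constants `K1 = 0.01`, `K2 = 0.03`, and
#' sample (n-1) normalisation for the window variances, with the dynamic
#' range defaulting to the reference's max - min.
#'
#' @param image Numeric matrix.
#' @param reference Numeric matrix of the same shape.
#' @param data_range Dynamic range `L`; default `max(reference) -
#'   min(reference)`.
#' @param win Window size (odd, default 7).
#' @return Scalar SSIM in `[-1, 1]`.
#' @examples
#' a <- matrix(rnorm(400), 20, 20)
#' ssim(a, a)  # exactly 1
#' @export
ssim <- function(image, reference, data_range = NULL, win = 7) {
  image <- as.matrix(image); reference <- as.matrix(reference)
  if (!all(dim(image) == dim(reference))) stop("shape mismatch")
  if (min(dim(image)) < win) stop("image smaller than the SSIM window")
  if (is.null(data_range)) data_range <- diff(range(reference))
  if (data_range <= 0) data_range <- 1
  np <- win * win
  covn <- np / (np - 1)
  mx <- box_mean_valid(image, win)
  my <- box_mean_valid(reference, win)
  mxx <- box_mean_valid(image * image, win)
  myy <- box_mean_valid(reference * reference, win)
  mxy <- box_mean_valid(image * reference, win)
  vx <- covn * (mxx - mx^2)
  vy <- covn * (myy - my^2)
  vxy <- covn * (mxy - mx * my)
  c1 <- (0.01 * data_range)^2
  c2 <- (0.03 * data_range)^2
  s <- ((2 * mx * my + c1) * (2 * vxy + c2)) /
    ((mx^2 + my^2 + c1) * (vx + vy + c2))
  mean(s)
}

# Exact mean over every fully-interior w x w window via an integral image.
box_mean_valid <- function(m, w) {
  S <- matrix(0, nrow(m) + 1, ncol(m) + 1)
  S[-1, -1] <- t(apply(apply(m, 2, cumsum), 1, cumsum))
  nzv <- nrow(m) - w + 1; nxv <- ncol(m) - w + 1
  i <- seq_len(nzv); j <- seq_len(nxv)
  (S[i + w, j + w, drop = FALSE] - S[i, j + w, drop = FALSE] -
     S[i + w, j, drop = FALSE] + S[i, j, drop = FALSE]) / (w * w)
}

#' Summarise the mean-variance trace of an inversion
#'
#' Reduces the per-iteration mean-variance trace to the features used for
#' quality monitoring: where the trace peaks, how far the final value sits
#' below the peak, and the least-squares slope over the trailing third.
#'
#' @param report An `inversion_report` from [run_inversion()], or a numeric
#'   trace.
#' @return List `peak_iteration`, `peak`, `final`, `final_peak_ratio`,
#'   `tail_slope`.
#' @export
variance_trend <- function(report) {
  trace <- if (inherits(report, "inversion_report")) report$mean_variance
           else as.numeric(report)
  if (length(trace) < 2) stop("trace too short")
  pk <- which.max(trace)
  list(peak_iteration = pk, peak = trace[pk], final = trace[length(trace)],
       final_peak_ratio = trace[length(trace)] / trace[pk],
       tail_slope = tail_slope(trace))
}

#' Flag a failed reconstruction from its variance trace
#'
#' A run is flagged when its mean-variance trace is still rising at the end
#' (positive tail slope) AND the final variance is large: more than
#' `factor` times a matched-run reference (when given) or the trace's own
#' early level (median of the first fifth of iterations). Both thresholds
#' are heuristics and configurable; a converging run has a falling trace and
#' is never flagged.
#'
#' @param report `inversion_report` or numeric trace (length >= 10).
#' @param reference Optional reference final mean variance from a trusted
#'   matched run.
#' @param factor Multiple of the reference/early level (default 2).
#' @return List `flag` (logical), `rule` (character), `tail_slope`,
#'   `final`, `threshold`.
#' @export
flag_failure <- function(report, reference = NULL, factor = 2) {
  trace <- if (inherits(report, "inversion_report")) report$mean_variance
           else as.numeric(report)
  if (length(trace) < 10) stop("trace must have at least 10 iterations")
  sl <- tail_slope(trace)
  fin <- trace[length(trace)]
  early <- stats::median(trace[seq_len(max(3, ceiling(length(trace) / 5)))])
  thr <- factor * early
  rule <- "tail_slope > 0 & final > factor * early_level"
  if (!is.null(reference)) {
    # either comparator may fire
    thr <- min(thr, factor * reference)
    rule <- "tail_slope > 0 & final > factor * min(reference, early_level)"
  }
  list(flag = (sl > 0) && (fin > thr), rule = rule, tail_slope = sl,
       final = fin, threshold = thr)
}

#' Localise artefacts in a variance image
#'
#' Block-averages the variance image, thresholds the blocks at
#' `median + k * MAD`, and returns the connected pixel regions above
#' threshold. Invariant to uniform scaling of the image. A spatially uniform
#' variance image yields an empty mask.
#'
#' @param variance_img Numeric matrix (per-pixel variance).
#' @param block Block size in pixels for averaging (default 5).
#' @param k MAD multiplier (default 5).
#' @return Logical matrix of the input shape; attribute `"n_regions"` holds
#'   the number of connected components (4-connectivity).
#' @export
artefact_mask <- function(variance_img, block = 5, k = 5) {
  v <- as.matrix(variance_img)
  if (!all(is.finite(v))) stop("variance image must be finite")
  nbz <- floor(nrow(v) / block); nbx <- floor(ncol(v) / block)
  if (nbz < 2 || nbx < 2) stop("image too small for the block size")
  blocks <- matrix(0, nbz, nbx)
  for (i in seq_len(nbz)) for (j in seq_len(nbx)) {
    blocks[i, j] <- mean(v[((i - 1) * block + 1):(i * block),
                           ((j - 1) * block + 1):(j * block)])
  }
  med <- stats::median(blocks)
  madv <- stats::mad(blocks)
  thr <- med + k * madv + 1e-12 * max(abs(blocks), 1e-300)
  hot <- blocks > thr
  mask <- matrix(FALSE, nrow(v), ncol(v))
  for (i in seq_len(nbz)) for (j in seq_len(nbx)) {
    if (hot[i, j])
      mask[((i - 1) * block + 1):(i * block),
           ((j - 1) * block + 1):(j * block)] <- TRUE
  }
  attr(mask, "n_regions") <- count_regions(hot)
  mask
}

# Connected components (4-connectivity) by flood fill on a logical matrix.
count_regions <- function(m) {
  lab <- matrix(0L, nrow(m), ncol(m))
  n <- 0L
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
    if (m[i, j] && lab[i, j] == 0L) {
      n <- n + 1L
      stack <- list(c(i, j))
      while (length(stack)) {
        p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
        if (p[1] < 1 || p[1] > nrow(m) || p[2] < 1 || p[2] > ncol(m)) next
        if (!m[p[1], p[2]] || lab[p[1], p[2]] != 0L) next
        lab[p[1], p[2]] <- n
        stack <- c(stack, list(p + c(1, 0)), list(p - c(1, 0)),
                   list(p + c(0, 1)), list(p - c(0, 1)))
      }
    }
  }
  n
}

#' Assemble a quality-control report
#'
#' @param report An `inversion_report`.
#' @param reference_image Optional ground-truth image for SSIM.
#' @param matched_reference Optional matched-run final mean variance for
#'   [flag_failure()].
#' @param block,k Passed to [artefact_mask()].
#' @return List of class `qc_report`: `ssim` (or `NA`),
#'   `mean_variance_trace`, `trend`, `failure`, `artefact_mask`.
#' @export
qc_report <- function(report, reference_image = NULL,
                      matched_reference = NULL, block = 5, k = 5) {
  s <- if (is.null(reference_image)) NA_real_
       else ssim(report$mu, as.matrix(reference_image))
  structure(list(ssim = s, mean_variance_trace = report$mean_variance,
                 trend = variance_trend(report),
                 failure = flag_failure(report, reference = matched_reference),
                 artefact_mask = artefact_mask(report$sigma2, block = block,
                                               k = k)),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> ssim %.3f, final variance %.4g, flagged: %s, hot regions: %d\n",
              x$ssim, x$trend$final, x$failure$flag,
              attr(x$artefact_mask, "n_regions")))
  invisible(x)
}
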