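#' Filter AChR clusters by area
#'
#' Retains acetylcholine-receptor clusters whose rasterized area is
#' strictly greater than `min_area` (default 5 um^2, the conventional
#' "bigger than 5 um^2" analysis rule).
#'
#' @param mask a [labeled_mask()] of AChR clusters.
#' @param min_area strict lower area bound in um^2 (default 5, >= 0).
#' @return data.frame with `label`, `n_pixels`, `area_um2`,
#'   `centroid_x_um`, `centroid_y_um` for the retained clusters; empty
#'   masks yield an empty data.frame.
#' @export
filter_achr_clusters <- function(mask, min_area = 5) {
  stopifnot_mask(mask)
  if (!is.numeric(min_area) || min_area < 0) stop("`min_area` must be >= 0")
  labs <- mask_labels(mask)
  ps <- mask$pixel_size
  rows <- lapply(labs, function(lab) {
    px <- which(mask$labels == lab, arr.ind = TRUE)
    data.frame(label = lab, n_pixels = nrow(px),
               area_um2 = nrow(px) * ps^2,
               centroid_x_um = (mean(px[, 2L]) - 1) * ps,
               centroid_y_um = (mean(px[, 1L]) - 1) * ps)
  })
  out <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(label = integer(0), n_pixels = integer(0),
               area_um2 = numeric(0), centroid_x_um = numeric(0),
               centroid_y_um = numeric(0))
  out <- out[out$area_um2 > min_area, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' AChR cluster counts per field and per myotube
#'
#' Summarizes retained clusters at the field level (count and mean size)
#' and assigns each cluster to the myotube containing its centroid;
#' clusters whose centroid falls on background are reported as unassigned.
#'
#' @param clusters output of [filter_achr_clusters()].
#' @param myotube_mask a [labeled_mask()] of myotubes, calibrated
#'   identically to the cluster mask.
#' @return List with `per_field` (data.frame: `n_clusters`,
#'   `mean_area_um2`), `per_myotube` (data.frame: `myotube_id`,
#'   `n_clusters`, including myotubes with zero clusters), and
#'   `n_unassigned`.
#' @export
clusters_per_field_and_myotube <- function(clusters, myotube_mask) {
  stopifnot_mask(myotube_mask)
  tubes <- mask_labels(myotube_mask)
  hit <- if (nrow(clusters) > 0L)
    centroid_in_mask(clusters, myotube_mask) else integer(0)
  per_myotube <- data.frame(
    myotube_id = tubes,
    n_clusters = vapply(tubes, function(t) sum(hit == t), integer(1)))
  list(per_field = data.frame(
         n_clusters = nrow(clusters),
         mean_area_um2 = if (nrow(clusters) > 0L)
           mean(clusters$area_um2) else NA_real_),
       per_myotube = per_myotube,
       n_unassigned = sum(hit == 0L))
}

#' Estimate the sarcomere (z-line) period from a striation line profile
#'
#' The period is the position of the dominant positive-lag peak of the
#' autocorrelation of the mean-subtracted intensity profile, refined to
#' sub-sample precision by parabolic interpolation of the peak and its two
#' neighbours (the period is only a few samples at realistic pixel sizes).
#' The mean distance between successive detected intensity peaks is
#' reported as an independent cross-check. At least 3 detectable peaks are
#' required; flat or aperiodic profiles (no autocorrelation peak above the
#' noise floor) are signalled as undefined.
#'
#' @param positions sample positions in micrometres, uniformly spaced; or a
#'   data.frame with columns `position_um` and `intensity`.
#' @param intensity profile intensity (a.u.). The estimate is invariant to
#'   intensity scaling and offset.
#' @return List with `period_um` (autocorrelation estimate),
#'   `peak_period_um` (mean inter-peak distance), `n_peaks`, and
#'   `acf_peak` (autocorrelation value at the period). Errors of class
#'   `myoquant_undefined` for flat/aperiodic profiles or fewer than 3
#'   peaks.
#' @export
estimate_sarcomere_period <- function(positions, intensity = NULL) {
  if (is.data.frame(positions)) {
    intensity <- positions$intensity
    positions <- positions$position_um
  }
  stopifnot(length(positions) == length(intensity), length(positions) >= 8L)
  dx <- diff(positions)
  if (max(dx) - min(dx) > 1e-6 * stats::median(dx))
    stop("profile must be uniformly sampled")
  dx <- stats::median(dx)
  x <- intensity - mean(intensity)
  n <- length(x)
  if (stats::sd(x) == 0)
    abort_undefined("period undefined: flat profile")
  # per-lag Pearson autocorrelation (per-segment means subtracted)
  lag_max <- floor(n / 2)
  r <- c(1, vapply(seq_len(lag_max), function(k)
    stats::cor(x[seq_len(n - k)], x[seq.int(k + 1L, n)]), numeric(1)))
  # local maxima at lag >= 2 samples
  k <- 3:(length(r) - 1L)
  is_max <- r[k] > r[k - 1L] & r[k] >= r[k + 1L]
  floor_level <- max(0.15, 3 / sqrt(n))
  cand <- k[is_max & r[k] > floor_level]
  if (length(cand) == 0L)
    abort_undefined("period undefined: no autocorrelation peak above the noise floor")
  # parabolic sub-sample interpolation of an autocorrelation local maximum
  refine <- function(kk) {
    denom <- r[kk - 1L] - 2 * r[kk] + r[kk + 1L]
    shift <- if (abs(denom) < 1e-12) 0 else
      0.5 * (r[kk - 1L] - r[kk + 1L]) / denom
    (kk - 1L) + shift                      # r[1] is lag 0
  }
  kk <- cand[which.max(r[cand])]
  lag1 <- refine(kk)
  # finite-window edge effects shift every harmonic peak by a nearly
  # constant number of samples; regressing the refined lags of the
  # harmonic peaks m*period on m cancels that shift in the slope
  lags <- lag1; ms <- 1
  m <- 2L
  while (m * lag1 + lag1 / 3 < lag_max) {
    lo <- max(2L, floor(m * lag1 - lag1 / 3))
    hi <- min(length(r) - 1L, ceiling(m * lag1 + lag1 / 3))
    seg <- (lo + 1L):(hi - 1L)
    loc <- seg[r[seg] > r[seg - 1L] & r[seg] >= r[seg + 1L] &
                 r[seg] > floor_level]
    if (length(loc) == 0L) break
    lags <- c(lags, refine(loc[which.max(r[loc])]))
    ms <- c(ms, m)
    m <- m + 1L
  }
  period <- if (length(ms) >= 2L)
    unname(stats::coef(stats::lm(lags ~ ms))[2L]) * dx
  else lag1 * dx
  # cross-check: mean distance between successive intensity peaks
  i <- 2:(n - 1L)
  thr <- mean(intensity) + 0.25 * (max(intensity) - mean(intensity))
  pk <- i[x[i] > x[i - 1L] & x[i] >= x[i + 1L] & intensity[i] > thr]
  # collapse plateaus/near-duplicates closer than half a period
  if (length(pk) > 1L)
    pk <- pk[c(TRUE, diff(positions[pk]) > period / 2)]
  if (length(pk) < 3L)
    abort_undefined("period undefined: fewer than 3 detectable peaks")
  list(period_um = period,
       peak_period_um = mean(diff(positions[pk])),
       n_peaks = length(pk),
       acf_peak = r[kk])
}

#' Label mask from a raw intensity image (convenience utility)
#'
#' Global Otsu threshold followed by connected-component labelling, via
#' EBImage. This is a generic, deliberately simple pre-step for producing
#' cluster masks from raw fluorescence when no dedicated segmentation is
#' available; it is not a calibrated segmentation procedure.
#'
#' @param intensity numeric matrix of raw fluorescence.
#' @param pixel_size micrometres per pixel.
#' @return A [labeled_mask()].
#' @export
label_from_intensity <- function(intensity, pixel_size) {
  if (!requireNamespace("EBImage", quietly = TRUE))
    stop("label_from_intensity() requires the EBImage package")
  img <- (intensity - min(intensity)) /
    max(max(intensity) - min(intensity), .Machine$double.eps)
  th <- EBImage::otsu(EBImage::Image(img))
  lab <- EBImage::bwlabel(EBImage::Image(img > th))
  labeled_mask(EBImage::imageData(lab), pixel_size)
}
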