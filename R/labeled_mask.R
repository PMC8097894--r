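#' Calibrated 2D label mask
#'
#' A `labeled_mask` couples an integer label image (0 = background, k > 0 =
#' object k) with its pixel size in micrometres per pixel. It is the
#' substrate of all morphometry in the package: areas are pixel counts times
#' `pixel_size^2`, distances are Euclidean distances between pixel centres
#' times `pixel_size`.
#'
#' @param labels integer matrix of non-negative labels (rows = image rows).
#' @param pixel_size pixel edge length in micrometres per pixel (> 0).
#' @return An object of class `labeled_mask`: a list with elements `labels`
#'   (integer matrix) and `pixel_size` (numeric scalar).
#' @examples
#' m <- labeled_mask(matrix(c(0, 1, 1, 0), 2, 2), pixel_size = 0.5)
#' mask_labels(m)
#' @export
labeled_mask <- function(labels, pixel_size) {
  if (is.data.frame(labels)) labels <- as.matrix(labels)
  if (!is.matrix(labels) || !is.numeric(labels))
    stop("`labels` must be a numeric/integer matrix")
  if (any(!is.finite(labels)) || any(labels < 0) ||
      any(labels != round(labels)))
    stop("`labels` must contain non-negative integers")
  storage.mode(labels) <- "integer"
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L ||
      !is.finite(pixel_size) || pixel_size <= 0)
    stop("`pixel_size` must be a single positive number (um/px)")
  structure(list(labels = labels, pixel_size = as.numeric(pixel_size)),
            class = "labeled_mask")
}

#' @export
print.labeled_mask <- function(x, ...) {
  labs <- mask_labels(x)
  cat(sprintf("<labeled_mask> %d x %d px @ %g um/px, %d object(s)\n",
              nrow(x$labels), ncol(x$labels), x$pixel_size, length(labs)))
  invisible(x)
}

stopifnot_mask <- function(mask) {
  if (!inherits(mask, "labeled_mask"))
    stop("expected a `labeled_mask` (see labeled_mask())")
  invisible(mask)
}

#' Labels present in a mask
#'
#' @param mask a [labeled_mask()].
#' @return Sorted integer vector of the object labels (> 0) in the mask.
#' @export
mask_labels <- function(mask) {
  stopifnot_mask(mask)
  labs <- unique(as.vector(mask$labels))
  sort(labs[labs > 0L])
}

#' Object areas in square micrometres
#'
#' Area is the rasterized area: pixel count times `pixel_size^2`.
#'
#' @param mask a [labeled_mask()].
#' @return Named numeric vector of areas, one entry per label.
#' @export
label_areas <- function(mask) {
  stopifnot_mask(mask)
  labs <- mask_labels(mask)
  if (length(labs) == 0L) return(stats::setNames(numeric(0), character(0)))
  counts <- tabulate(mask$labels, nbins = max(labs))[labs]
  stats::setNames(counts * mask$pixel_size^2, labs)
}

#' Read / write label masks as 16-bit TIFF
#'
#' Masks are stored as single-channel 16-bit TIFF, one integer label per
#' pixel. The pixel size is not stored in the file and must be supplied on
#' read.
#'
#' @param path file path.
#' @param pixel_size micrometres per pixel of the stored image.
#' @return `read_label_mask()` returns a [labeled_mask()];
#'   `write_label_mask()` returns `path` invisibly.
#' @export
read_label_mask <- function(path, pixel_size) {
  img <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  labeled_mask(img, pixel_size)
}

#' @param mask a [labeled_mask()] with labels < 65536.
#' @rdname read_label_mask
#' @export
write_label_mask <- function(mask, path) {
  stopifnot_mask(mask)
  if (max(mask$labels) > 65535L)
    stop("labels exceed the 16-bit range of the TIFF container")
  tiff::writeTIFF(mask$labels / 65535, path, bits.per.sample = 16L,
                  compression = "none")
  invisible(path)
}

# Boundary pixels of one label under 8-connectivity: label pixels with at
# least one of the 8 neighbours outside the image or carrying a different
# value. Returns an n x 2 matrix of (row, col) indices.
boundary_pixels <- function(labels, label) {
  idx <- which(labels == label, arr.ind = TRUE)
  if (nrow(idx) == 0L)
    stop(sprintf("label %s absent from mask", format(label)))
  nr <- nrow(labels); nc <- ncol(labels)
  on_boundary <- logical(nrow(idx))
  shifts <- cbind(dr = c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L),
                  dc = c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L))
  for (s in seq_len(nrow(shifts))) {
    rr <- idx[, 1L] + shifts[s, 1L]
    cc <- idx[, 2L] + shifts[s, 2L]
    outside <- rr < 1L | rr > nr | cc < 1L | cc > nc
    differs <- outside
    if (any(!outside))
      differs[!outside] <- labels[cbind(rr[!outside], cc[!outside])] != label
    on_boundary <- on_boundary | differs
    if (all(on_boundary)) break
  }
  idx[on_boundary, , drop = FALSE]
}

# Minimal Euclidean distance between two point sets (n x 2 matrices),
# computed exactly over all pairs.
min_cross_distance <- function(a, b) {
  d2 <- outer(a[, 1L], b[, 1L], "-")^2 + outer(a[, 2L], b[, 2L], "-")^2
  sqrt(min(d2))
}

#' Ellipse shape metrics of one labelled object
#'
#' Fits the ellipse with the same central second moments as the object's
#' pixel set (with the 1/12 per-pixel variance correction, so a single
#' pixel is exactly isotropic) and reports its eccentricity
#' `sqrt(1 - lambda_minor / lambda_major)` and the orientation of the major
#' axis. A perfect circle has eccentricity 0; an infinitely elongated
#' object approaches 1.
#'
#' Coordinates are 0-based pixel indices with x along columns and y along
#' rows; orientation is the angle of the major axis against the +x axis in
#' degrees, counterclockwise positive as displayed (i.e. with y pointing
#' up), wrapped to `[-90, 90)`.
#'
#' @param mask a [labeled_mask()].
#' @param label object label present in the mask.
#' @return List with `eccentricity` (in `[0, 1]`), `orientation` (degrees in
#'   `[-90, 90)`; 0 with `degenerate = TRUE` when the object is isotropic
#'   and the axis direction is undefined), and `degenerate` (logical).
#' @export
shape_metrics <- function(mask, label) {
  stopifnot_mask(mask)
  px <- which(mask$labels == label, arr.ind = TRUE)
  if (nrow(px) == 0L)
    stop(sprintf("label %s absent from mask", format(label)))
  x <- px[, 2L] - 1
  y <- -(px[, 1L] - 1)          # y up => counterclockwise-positive angles
  x <- x - mean(x); y <- y - mean(y)
  sxx <- mean(x^2) + 1 / 12
  syy <- mean(y^2) + 1 / 12
  sxy <- mean(x * y)
  spread <- sqrt((sxx - syy)^2 + 4 * sxy^2)
  lmax <- (sxx + syy + spread) / 2
  lmin <- (sxx + syy - spread) / 2
  degenerate <- spread < 1e-12 * max(lmax, 1)
  ecc <- sqrt(max(0, 1 - lmin / lmax))
  theta <- if (degenerate) 0 else 0.5 * atan2(2 * sxy, sxx - syy) * 180 / pi
  if (theta >= 90) theta <- theta - 180
  list(eccentricity = ecc, orientation = theta, degenerate = degenerate)
}

#' Per-nucleus records from a label mask
#'
#' Computes, for every object in the mask, its rasterized area, centroid
#' (micrometres, image coordinates: x along columns, y along rows),
#' ellipse eccentricity and major-axis orientation (see [shape_metrics()]),
#' and an optional marker-positivity flag.
#'
#' @param mask a [labeled_mask()].
#' @param marker optional marker positivity: either a logical vector named
#'   by label, or a data.frame with columns `label` and `positive`.
#' @return A data.frame with one row per object: `label`, `n_pixels`,
#'   `area_um2`, `centroid_x_um`, `centroid_y_um`, `eccentricity`,
#'   `orientation_deg`, `degenerate`, `marker_positive`.
#' @export
nucleus_records <- function(mask, marker = NULL) {
  stopifnot_mask(mask)
  labs <- mask_labels(mask)
  ps <- mask$pixel_size
  empty <- data.frame(label = integer(0), n_pixels = integer(0),
                      area_um2 = numeric(0), centroid_x_um = numeric(0),
                      centroid_y_um = numeric(0), eccentricity = numeric(0),
                      orientation_deg = numeric(0), degenerate = logical(0),
                      marker_positive = logical(0))
  if (length(labs) == 0L) return(empty)
  rows <- lapply(labs, function(lab) {
    px <- which(mask$labels == lab, arr.ind = TRUE)
    sm <- shape_metrics(mask, lab)
    data.frame(label = lab,
               n_pixels = nrow(px),
               area_um2 = nrow(px) * ps^2,
               centroid_x_um = (mean(px[, 2L]) - 1) * ps,
               centroid_y_um = (mean(px[, 1L]) - 1) * ps,
               eccentricity = sm$eccentricity,
               orientation_deg = sm$orientation,
               degenerate = sm$degenerate)
  })
  out <- do.call(rbind, rows)
  out$marker_positive <- NA
  if (!is.null(marker)) {
    if (is.data.frame(marker)) {
      stopifnot(all(c("label", "positive") %in% names(marker)))
      marker <- stats::setNames(as.logical(marker$positive),
                                marker$label)
    }
    hit <- match(out$label, as.integer(names(marker)))
    out$marker_positive <- as.logical(marker)[hit]
  }
  rownames(out) <- NULL
  out
}
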