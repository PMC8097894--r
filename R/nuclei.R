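#' Filter nuclei by individual area
#'
#' Keeps nuclei whose rasterized area lies inside a closed interval,
#' mirroring the morphometry convention of analysing nuclei with individual
#' area between 40 and 200 um^2 (both bounds inclusive).
#'
#' @param mask a [labeled_mask()].
#' @param min_area,max_area area bounds in um^2 (defaults 40 and 200),
#'   `min_area < max_area`; both inclusive.
#' @param records optional precomputed [nucleus_records()] for `mask`.
#' @return The subset of the per-nucleus records with
#'   `min_area <= area_um2 <= max_area`. An empty mask yields an empty
#'   data.frame, not an error.
#' @export
filter_nuclei_by_area <- function(mask, min_area = 40, max_area = 200,
                                  records = NULL) {
  if (!(is.numeric(min_area) && is.numeric(max_area) && min_area < max_area))
    stop("`min_area` must be smaller than `max_area`")
  if (is.null(records)) records <- nucleus_records(mask)
  keep <- records$area_um2 >= min_area & records$area_um2 <= max_area
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Single-linkage clustering of nuclei by border-to-border distance
#'
#' Two nuclei are neighbours when the minimal Euclidean distance between
#' their boundary pixel centres (8-connectivity boundary) is strictly below
#' `max_gap` micrometres; clusters are the connected components of the
#' resulting graph (single linkage, so a cluster may span more than
#' `max_gap` end to end). Nuclei in a cluster of size one are isolated.
#'
#' @param mask a [labeled_mask()].
#' @param records optional per-nucleus records restricted to the nuclei to
#'   cluster (e.g. the output of [filter_nuclei_by_area()]); defaults to all
#'   objects in the mask. Every `label` must be present in the mask.
#' @param max_gap neighbour threshold in micrometres (default 3, strict
#'   inequality).
#' @return A data.frame with `label`, `cluster_id` (1-based, in order of
#'   first appearance), `cluster_size` and `is_isolated`.
#' @export
cluster_nuclei <- function(mask, records = NULL, max_gap = 3) {
  stopifnot_mask(mask)
  if (!is.numeric(max_gap) || max_gap < 0) stop("`max_gap` must be >= 0")
  labs <- if (is.null(records)) mask_labels(mask) else as.integer(records$label)
  present <- mask_labels(mask)
  missing <- setdiff(labs, present)
  if (length(missing) > 0L)
    stop(sprintf("record label(s) absent from mask: %s",
                 paste(missing, collapse = ", ")))
  n <- length(labs)
  out <- data.frame(label = labs, cluster_id = NA_integer_,
                    cluster_size = NA_integer_, is_isolated = NA)
  if (n == 0L) return(out)

  ps <- mask$pixel_size
  bps <- lapply(labs, function(l) boundary_pixels(mask$labels, l) * ps)
  ctr <- t(vapply(bps, colMeans, numeric(2)))
  rad <- vapply(seq_len(n), function(i) {
    sqrt(max((bps[[i]][, 1L] - ctr[i, 1L])^2 +
             (bps[[i]][, 2L] - ctr[i, 2L])^2))
  }, numeric(1))

  # union-find over pairs, pruned by a centroid-distance lower bound
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(max(0L, n - 1L))) {
    for (j in seq.int(i + 1L, n)) {
      lower <- sqrt(sum((ctr[i, ] - ctr[j, ])^2)) - rad[i] - rad[j]
      if (lower >= max_gap) next
      if (min_cross_distance(bps[[i]], bps[[j]]) < max_gap) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  out$cluster_id <- match(roots, unique(roots))
  sizes <- tabulate(out$cluster_id)
  out$cluster_size <- sizes[out$cluster_id]
  out$is_isolated <- out$cluster_size == 1L
  out
}

#' Fusion index
#'
#' Fraction of nuclei residing within myotubes: the number of nuclei whose
#' centroid falls on a non-zero pixel of the myotube mask, divided by the
#' total number of nuclei. A classic differentiation readout.
#'
#' @param nuclei_mask,myotube_mask [labeled_mask()]s with identical shape
#'   and pixel size.
#' @param records optional precomputed/filtered [nucleus_records()] for
#'   `nuclei_mask`.
#' @return Fraction in `[0, 1]`. Signals an error of class
#'   `myoquant_undefined` when there are no nuclei.
#' @export
fusion_index <- function(nuclei_mask, myotube_mask, records = NULL) {
  stopifnot_mask(nuclei_mask); stopifnot_mask(myotube_mask)
  if (!identical(dim(nuclei_mask$labels), dim(myotube_mask$labels)))
    stop("nuclei and myotube masks must share the same shape")
  if (nuclei_mask$pixel_size != myotube_mask$pixel_size)
    stop("nuclei and myotube masks must share the same pixel size")
  if (is.null(records)) records <- nucleus_records(nuclei_mask)
  if (nrow(records) == 0L)
    abort_undefined("fusion index undefined: no nuclei")
  mean(centroid_in_mask(records, myotube_mask) > 0L)
}

# Myotube label under each record's centroid (0 = background); centroids in
# micrometres are mapped back to the nearest pixel, clamped to the image.
centroid_in_mask <- function(records, mask) {
  ps <- mask$pixel_size
  r <- pmin(pmax(round(records$centroid_y_um / ps) + 1L, 1L),
            nrow(mask$labels))
  c <- pmin(pmax(round(records$centroid_x_um / ps) + 1L, 1L),
            ncol(mask$labels))
  mask$labels[cbind(r, c)]
}

#' Marker-positive fraction
#'
#' Fraction of retained nuclei positive for a nuclear marker (e.g. MEF2C,
#' MyoD or Pax7 immunostaining).
#'
#' @param records per-nucleus records (the retained population).
#' @param positive logical vector, one flag per record; defaults to the
#'   `marker_positive` column of `records`.
#' @return Fraction in `[0, 1]`; errors (class `myoquant_undefined`) when no
#'   nuclei are retained, and errors when flags are missing or mismatched.
#' @export
marker_fraction <- function(records, positive = records$marker_positive) {
  if (nrow(records) == 0L)
    abort_undefined("marker fraction undefined: no retained nuclei")
  positive <- as.logical(positive)
  if (length(positive) != nrow(records) || anyNA(positive))
    stop("`positive` must supply one non-missing flag per retained nucleus")
  mean(positive)
}

#' Per-field summary of nuclei arrangement
#'
#' Aggregates one acquisition field into the study-level readouts: number
#' of retained nuclei, median cluster size, median eccentricity of the
#' isolated nuclei, and the orientation histogram of isolated nuclei.
#' Medians are taken over their defining populations: cluster sizes over
#' clusters (optionally excluding singletons), eccentricities over isolated
#' nuclei only.
#'
#' @param records per-nucleus records (after area filtering).
#' @param assignments output of [cluster_nuclei()] for the same records.
#' @param include_singletons include size-1 clusters in the median cluster
#'   size (default TRUE).
#' @param bin_width orientation histogram bin width in degrees (default 10;
#'   bins cover `[-90, 90)`).
#' @param fusion_index,marker_fraction optional precomputed fractions to
#'   carry into the summary.
#' @return List of class `field_summary` with `n_nuclei_retained`,
#'   `median_cluster_size`, `median_eccentricity`, `orientation_histogram`
#'   (named counts), `fusion_index`, `marker_fraction`. Undefined medians
#'   are `NA` with a warning of class `myoquant_undefined_warning`.
#' @export
summarize_field <- function(records, assignments, include_singletons = TRUE,
                            bin_width = 10, fusion_index = NA_real_,
                            marker_fraction = NA_real_) {
  if (!all(records$label %in% assignments$label))
    stop("every record must have a cluster assignment")
  a <- assignments[match(records$label, assignments$label), , drop = FALSE]
  sizes <- a$cluster_size[!duplicated(a$cluster_id)]
  if (!include_singletons) sizes <- sizes[sizes >= 2L]
  med_size <- if (length(sizes) == 0L) {
    warn_undefined("median cluster size undefined: no qualifying clusters")
    NA_real_
  } else stats::median(sizes)
  iso <- records[a$is_isolated, , drop = FALSE]
  med_ecc <- if (nrow(iso) == 0L) {
    warn_undefined("median eccentricity undefined: no isolated nuclei")
    NA_real_
  } else stats::median(iso$eccentricity)
  breaks <- seq(-90, 90, by = bin_width)
  ori <- iso$orientation_deg[!iso$degenerate]
  hist_counts <- if (length(ori) > 0L) {
    table(cut(ori, breaks = breaks, right = FALSE))
  } else table(cut(numeric(0), breaks = breaks, right = FALSE))
  structure(list(n_nuclei_retained = nrow(records),
                 median_cluster_size = med_size,
                 median_eccentricity = med_ecc,
                 orientation_histogram = hist_counts,
                 fusion_index = fusion_index,
                 marker_fraction = marker_fraction),
            class = "field_summary")
}

#' @export
print.field_summary <- function(x, ...) {
  cat(sprintf(paste0("<field_summary> %d nuclei retained | median cluster ",
                     "size %s | median eccentricity (isolated) %s\n"),
              x$n_nuclei_retained, format(x$median_cluster_size),
              format(round(x$median_eccentricity, 3))))
  if (!is.na(x$fusion_index))
    cat(sprintf("  fusion index %.3f\n", x$fusion_index))
  if (!is.na(x$marker_fraction))
    cat(sprintf("  marker-positive fraction %.3f\n", x$marker_fraction))
  invisible(x)
}
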