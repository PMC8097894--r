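# Ground-truth-annotated synthetic inputs for every pipeline stage. All
# generators are pure functions of their parameters including `seed`
# (RNG state is scoped with withr::with_seed and restored afterwards).

# Axial angles in degrees in [-90, 90). concentration 0 => uniform;
# otherwise a wrapped-normal on the doubled angle with variance
# 1/concentration, so large values concentrate near 0 (the x-axis).
sample_axial_angles <- function(n, concentration) {
  if (concentration <= 0) return(stats::runif(n, -90, 90))
  phi <- stats::rnorm(n, 0, 1 / sqrt(concentration))
  phi <- atan2(sin(phi), cos(phi))      # wrap the doubled angle
  theta <- phi / 2 * 180 / pi
  ifelse(theta >= 90, theta - 180, theta)
}

# Pixels (row, col) of a filled ellipse with centre (cr, cc) in 1-based
# fractional pixel coordinates, semi-axes in pixels, orientation in degrees
# counterclockwise from +x (y up). Clipped to an nr x nc image.
rasterize_ellipse <- function(cr, cc, a, b, theta_deg, nr, nc) {
  th <- theta_deg * pi / 180
  r_rng <- max(1L, floor(cr - a - 1)):min(nr, ceiling(cr + a + 1))
  c_rng <- max(1L, floor(cc - a - 1)):min(nc, ceiling(cc + a + 1))
  if (length(r_rng) == 0L || length(c_rng) == 0L)
    return(matrix(integer(0), 0L, 2L))
  dx <- rep(c_rng - cc, each = length(r_rng))
  dy <- rep(-(r_rng - cr), times = length(c_rng))
  u <- dx * cos(th) + dy * sin(th)
  v <- -dx * sin(th) + dy * cos(th)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  cbind(row = rep(r_rng, times = length(c_rng))[inside],
        col = rep(c_rng, each = length(r_rng))[inside])
}

# Directional radius of an ellipse: distance from centre to boundary along
# polar angle `phi` (degrees, same frame as the orientation).
ellipse_radius_at <- function(a, b, theta_deg, phi_deg) {
  psi <- (phi_deg - theta_deg) * pi / 180
  a * b / sqrt((b * cos(psi))^2 + (a * sin(psi))^2)
}

# Boundary subset of a standalone pixel set (8-connectivity), without a
# full image: pixels with at least one of the 8 neighbours outside the set.
pixelset_boundary <- function(px) {
  if (nrow(px) <= 2L) return(px)
  r0 <- min(px[, 1L]) - 2L; c0 <- min(px[, 2L]) - 2L
  rr <- px[, 1L] - r0; cc <- px[, 2L] - c0
  m <- matrix(FALSE, max(rr) + 2L, max(cc) + 2L)
  m[cbind(rr, cc)] <- TRUE
  interior <- m[cbind(rr - 1L, cc)] & m[cbind(rr + 1L, cc)] &
    m[cbind(rr, cc - 1L)] & m[cbind(rr, cc + 1L)] &
    m[cbind(rr - 1L, cc - 1L)] & m[cbind(rr - 1L, cc + 1L)] &
    m[cbind(rr + 1L, cc - 1L)] & m[cbind(rr + 1L, cc + 1L)]
  px[!interior, , drop = FALSE]
}

# indices placed after a checkpoint (exclusive) up to k (inclusive)
members_of <- function(k0, k) if (k > k0) seq.int(k0 + 1L, k) else integer(0)

placement_error <- function(what) {
  stop(errorCondition(
    sprintf("placement failure: could not place %s without violating spacing constraints; enlarge the field or reduce the object count", what),
    class = c("myoquant_placement_error", "error")))
}

#' Generate a synthetic nuclei field with ground truth
#'
#' Renders non-overlapping nuclei as filled ellipses on a pixel grid,
#' arranged in spatial clusters: consecutive members of a cluster are
#' placed with a border-to-border gap of at most `intra_cluster_gap`
#' micrometres, while nuclei of different clusters are kept at least
#' `min_separation` micrometres apart. With the default thresholds a
#' border-to-border clustering at 3 um recovers the generated cluster
#' structure. The emitted ground truth records the rasterized area (pixel
#' count times `pixel_size^2` — what morphometry measures), the analytic
#' eccentricity and orientation of each ellipse, and the cluster id.
#'
#' @param n_nuclei number of nuclei (>= 0).
#' @param field_size image size in pixels, `c(rows, cols)`.
#' @param pixel_size micrometres per pixel (> 0).
#' @param cluster_size_prob probability vector over cluster sizes
#'   `1..length(cluster_size_prob)`.
#' @param mean_eccentricity,ecc_sd mean and spread of per-nucleus analytic
#'   eccentricity; draws are clamped to `[0, 0.95]`.
#' @param orientation_concentration 0 for uniformly random major-axis
#'   orientations; larger values align nuclei to the x-axis.
#' @param intra_cluster_gap maximal border-to-border gap (um) between a new
#'   cluster member and its anchor; keep below the clustering threshold.
#' @param min_separation minimal border-to-border distance (um) between
#'   nuclei of different clusters; keep above the clustering threshold.
#' @param area_range min and max analytic ellipse area in um^2.
#' @param seed integer RNG seed; identical parameters + seed give
#'   byte-identical output.
#' @param max_retries placement retries per nucleus before signalling a
#'   placement failure (condition class `myoquant_placement_error`).
#' @return List of class `nuclei_field` with `mask` (a [labeled_mask()],
#'   labels `1..n_nuclei`) and `truth` (data.frame: `label`, `cluster_id`,
#'   `n_pixels`, `area_um2` rasterized, `eccentricity`, `orientation_deg`,
#'   `centroid_x_um`, `centroid_y_um`).
#' @export
generate_nuclei_field <- function(n_nuclei,
                                  field_size = c(640L, 640L),
                                  pixel_size = 0.325,
                                  cluster_size_prob = c(0.5, 0.25, 0.15, 0.1),
                                  mean_eccentricity = 0.6,
                                  ecc_sd = 0.1,
                                  orientation_concentration = 0,
                                  intra_cluster_gap = 1.5,
                                  min_separation = 4,
                                  area_range = c(60, 180),
                                  seed = 1L,
                                  max_retries = 1000L) {
  stopifnot(n_nuclei >= 0, pixel_size > 0, length(field_size) == 2L,
            all(cluster_size_prob >= 0), sum(cluster_size_prob) > 0,
            area_range[1] > 0, area_range[1] < area_range[2])
  nr <- as.integer(field_size[1L]); nc <- as.integer(field_size[2L])
  empty_truth <- data.frame(label = integer(0), cluster_id = integer(0),
                            n_pixels = integer(0), area_um2 = numeric(0),
                            eccentricity = numeric(0),
                            orientation_deg = numeric(0),
                            centroid_x_um = numeric(0),
                            centroid_y_um = numeric(0))
  labels <- matrix(0L, nr, nc)
  if (n_nuclei == 0L)
    return(structure(list(mask = labeled_mask(labels, pixel_size),
                          truth = empty_truth), class = "nuclei_field"))

  withr::with_seed(seed, {
    sizes <- integer(0)
    while (sum(sizes) < n_nuclei)
      sizes <- c(sizes, sample.int(length(cluster_size_prob), 1L,
                                   prob = cluster_size_prob))
    sizes[length(sizes)] <- sizes[length(sizes)] -
      (sum(sizes) - n_nuclei)
    sizes <- sizes[sizes > 0L]

    ecc_all <- pmin(pmax(stats::rnorm(n_nuclei, mean_eccentricity, ecc_sd),
                         0), 0.95)
    ori_all <- sample_axial_angles(n_nuclei, orientation_concentration)
    area_all <- stats::runif(n_nuclei, area_range[1L], area_range[2L])

    placed_px <- vector("list", n_nuclei)   # pixel sets
    placed_bd <- vector("list", n_nuclei)   # boundary pixels, um
    placed_ctr <- matrix(NA_real_, n_nuclei, 2L)
    placed_rad <- numeric(n_nuclei)
    cluster_of <- integer(n_nuclei)
    truth <- vector("list", n_nuclei)
    k <- 0L

    for (ci in seq_along(sizes)) {
      # a cluster whose member placement gets stuck (e.g. the anchor drew
      # a hemmed-in spot) is torn down and retried elsewhere as a whole
      k0 <- k
      cluster_done <- FALSE
      for (restart in seq_len(20L)) {
        for (idx in members_of(k0, k)) {
          labels[placed_px[[idx]]] <- 0L
          placed_px[idx] <- list(NULL); placed_bd[idx] <- list(NULL)
          cluster_of[idx] <- 0L; truth[idx] <- list(NULL)
        }
        k <- k0
        cluster_failed <- FALSE
      members <- integer(0)
      for (m in seq_len(sizes[ci])) {
        k <- k + 1L
        a_um <- sqrt(area_all[k] / (pi * sqrt(1 - ecc_all[k]^2)))
        b_um <- a_um * sqrt(1 - ecc_all[k]^2)
        a <- a_um / pixel_size; b <- b_um / pixel_size
        ok <- FALSE
        for (try in seq_len(max_retries)) {
          if (m == 1L) {
            cr <- stats::runif(1, a + 2, nr - a - 1)
            cc <- stats::runif(1, a + 2, nc - a - 1)
          } else {
            # aim for a border gap inside (0, intra_cluster_gap] using the
            # directional radii of the two ellipses along the offset
            anchor <- truth[[sample(members, 1L)]]
            phi <- stats::runif(1, 0, 360)
            gap_target <- stats::runif(1, 0.35 * intra_cluster_gap,
                                       0.85 * intra_cluster_gap)
            d_um <- ellipse_radius_at(anchor$a_um, anchor$b_um,
                                      anchor$ori, phi) +
              ellipse_radius_at(a_um, b_um, ori_all[k], phi + 180) +
              gap_target
            cr <- anchor$cr - d_um * sin(phi * pi / 180) / pixel_size
            cc <- anchor$cc + d_um * cos(phi * pi / 180) / pixel_size
          }
          px <- rasterize_ellipse(cr, cc, a, b, ori_all[k], nr, nc)
          if (nrow(px) == 0L) next
          # stay inside the field
          if (min(px[, 1L]) <= 1L || max(px[, 1L]) >= nr ||
              min(px[, 2L]) <= 1L || max(px[, 2L]) >= nc) next
          if (any(labels[px] != 0L)) next
          bd_um <- pixelset_boundary(px) * pixel_size
          ctr <- colMeans(bd_um)
          rad <- sqrt(max((bd_um[, 1L] - ctr[1L])^2 +
                          (bd_um[, 2L] - ctr[2L])^2))
          viol <- FALSE; near_anchor <- m == 1L
          for (idx in seq_len(k - 1L)) {
            lower <- sqrt(sum((placed_ctr[idx, ] - ctr)^2)) -
              placed_rad[idx] - rad
            if (cluster_of[idx] == ci) {
              if (!near_anchor && lower <= intra_cluster_gap &&
                  min_cross_distance(bd_um, placed_bd[[idx]]) <=
                    intra_cluster_gap)
                near_anchor <- TRUE
            } else if (lower < min_separation &&
                       min_cross_distance(bd_um, placed_bd[[idx]]) <
                         min_separation) {
              viol <- TRUE; break
            }
          }
          if (viol || !near_anchor) next
          labels[px] <- k
          placed_px[[k]] <- px
          placed_bd[[k]] <- bd_um
          placed_ctr[k, ] <- ctr
          placed_rad[k] <- rad
          cluster_of[k] <- ci
          truth[[k]] <- list(label = k, cluster_id = ci,
                             n_pixels = nrow(px),
                             ecc = ecc_all[k], ori = ori_all[k],
                             cr = cr, cc = cc, a_um = a_um, b_um = b_um)
          members <- c(members, k)
          ok <- TRUE
          break
        }
        if (!ok) { cluster_failed <- TRUE; break }
      }
        if (!cluster_failed) { cluster_done <- TRUE; break }
      }
      if (!cluster_done)
        placement_error(sprintf("cluster %d (%d nuclei)", ci, sizes[ci]))
    }
    truth_df <- do.call(rbind, lapply(truth, function(t) {
      px <- placed_px[[t$label]]
      data.frame(label = t$label, cluster_id = t$cluster_id,
                 n_pixels = t$n_pixels,
                 area_um2 = t$n_pixels * pixel_size^2,
                 eccentricity = t$ecc, orientation_deg = t$ori,
                 centroid_x_um = (mean(px[, 2L]) - 1) * pixel_size,
                 centroid_y_um = (mean(px[, 1L]) - 1) * pixel_size)
    }))
    truth_df <- truth_df[order(truth_df$label), , drop = FALSE]
    rownames(truth_df) <- NULL
    structure(list(mask = labeled_mask(labels, pixel_size),
                   truth = truth_df),
              class = "nuclei_field")
  })
}

#' Study-condition parameter presets for nuclei fields
#'
#' Two presets emulating the contrast between myotubes grown on a flat
#' versus a nanopatterned (grooved) substrate: on flat surfaces nuclei
#' aggregate in large clusters (up to ~20 nuclei), are rounder and have no
#' preferred orientation; on the nanopattern clusters are smaller (up to
#' ~8), nuclei are elongated and aligned with the grooves (x-axis).
#'
#' @param condition `"flat"` or `"nanopattern"`.
#' @return Named list of arguments for [generate_nuclei_field()].
#' @export
nuclei_condition_params <- function(condition = c("flat", "nanopattern")) {
  condition <- match.arg(condition)
  if (condition == "flat") {
    list(cluster_size_prob = stats::dgeom(0:19, prob = 0.25),
         mean_eccentricity = 0.55, ecc_sd = 0.12,
         orientation_concentration = 0)
  } else {
    list(cluster_size_prob = stats::dgeom(0:7, prob = 0.45),
         mean_eccentricity = 0.85, ecc_sd = 0.06,
         orientation_concentration = 8)
  }
}

#' Electric-field burst stimulation protocol
#'
#' Repetitive bursts of field pulses: by default 1 s of 10 Hz pulses (2 ms
#' each) every 10 s for 3 min, the standard myotube pacing protocol. Burst
#' onsets are `0, inter_burst_period, ...` relative to stimulation start,
#' for every burst that completes within `total_duration`.
#'
#' @param burst_duration burst length in seconds (default 1).
#' @param intra_burst_rate pulse rate within a burst, Hz (default 10).
#' @param pulse_width_ms single pulse width in ms (metadata only,
#'   default 2).
#' @param inter_burst_period burst period in seconds (default 10), must
#'   exceed `burst_duration`.
#' @param total_duration stimulation length in seconds (default 180).
#' @return Object of class `stim_protocol`.
#' @export
stim_protocol <- function(burst_duration = 1, intra_burst_rate = 10,
                          pulse_width_ms = 2, inter_burst_period = 10,
                          total_duration = 180) {
  stopifnot(burst_duration > 0, intra_burst_rate > 0,
            inter_burst_period > burst_duration, total_duration > 0)
  structure(list(burst_duration = burst_duration,
                 intra_burst_rate = intra_burst_rate,
                 pulse_width_ms = pulse_width_ms,
                 inter_burst_period = inter_burst_period,
                 total_duration = total_duration),
            class = "stim_protocol")
}

#' Burst onset times of a protocol
#'
#' @param protocol a [stim_protocol()].
#' @param stim_start time of the first burst onset in the recording's
#'   clock, seconds (default 0).
#' @return Numeric vector of onset times; 18 bursts for the default
#'   protocol. Errors if the protocol is shorter than one burst.
#' @export
burst_onsets <- function(protocol, stim_start = 0) {
  stopifnot(inherits(protocol, "stim_protocol"))
  if (protocol$total_duration < protocol$burst_duration)
    stop("protocol duration is shorter than one burst")
  stim_start + seq(0, protocol$total_duration - protocol$burst_duration,
                   by = protocol$inter_burst_period)
}

#' Generate a synthetic burst-locked calcium trace
#'
#' Produces a raw fluorescence time series sampled at `sampling_rate`:
#' a flat baseline of `baseline_duration` seconds, then one transient per
#' burst. Each transient rises instantaneously at the first sample at or
#' after its burst onset (the ~3.3 Hz acquisition cannot resolve the rise)
#' and decays monoexponentially with `decay_tau`. Transient amplitudes
#' decrease log-linearly across bursts so that the last-to-first amplitude
#' ratio equals `rundown_fraction`. With `responder = FALSE` the first
#' amplitude is capped at 0.3 dF/F0, below the 0.5 responder threshold.
#'
#' @param protocol a [stim_protocol()].
#' @param sampling_rate acquisition rate in Hz (default 3.3).
#' @param baseline_F baseline fluorescence in a.u. (> 0).
#' @param responder logical; `FALSE` forces a sub-threshold response.
#' @param first_amplitude first-transient amplitude in dF/F0 units.
#' @param decay_tau monoexponential decay constant in seconds (> 0).
#' @param rundown_fraction last/first amplitude ratio in (0, 1].
#' @param noise_sd Gaussian noise SD on raw fluorescence, a.u.
#' @param baseline_duration pre-stimulus baseline length in seconds.
#' @param seed integer RNG seed.
#' @return List of class `synthetic_trace`: `trace` (data.frame `time_s`,
#'   `F`), `protocol`, and `truth` (list with `stim_start`, `onsets`,
#'   `sampled_onsets`, `amplitudes`, `decay_tau`, `rundown_fraction`,
#'   `responder`, `baseline_F`).
#' @export
generate_trace <- function(protocol = stim_protocol(), sampling_rate = 3.3,
                           baseline_F = 800, responder = TRUE,
                           first_amplitude = 1.2, decay_tau = 2,
                           rundown_fraction = 0.8, noise_sd = 0,
                           baseline_duration = 5, seed = 1L) {
  stopifnot(inherits(protocol, "stim_protocol"), sampling_rate > 0,
            decay_tau > 0, baseline_F > 0, noise_sd >= 0,
            rundown_fraction > 0, rundown_fraction <= 1,
            baseline_duration >= 0)
  onsets <- burst_onsets(protocol, stim_start = baseline_duration)
  nb <- length(onsets)
  amp1 <- if (!responder) min(first_amplitude, 0.3) else first_amplitude
  k <- seq_len(nb)
  amps <- if (nb == 1L) amp1 else
    amp1 * rundown_fraction^((k - 1) / (nb - 1))
  time <- seq(0, baseline_duration + protocol$total_duration,
              by = 1 / sampling_rate)
  sampled_onsets <- vapply(onsets, function(o)
    time[which(time >= o - 1e-9)[1L]], numeric(1))
  s <- numeric(length(time))
  for (i in k) {
    on <- time >= sampled_onsets[i] - 1e-9
    s[on] <- s[on] + amps[i] * exp(-(time[on] - sampled_onsets[i]) /
                                     decay_tau)
  }
  F_raw <- withr::with_seed(seed,
    baseline_F * (1 + s) + stats::rnorm(length(time), 0, noise_sd))
  structure(list(trace = data.frame(time_s = time, F = F_raw),
                 protocol = protocol,
                 truth = list(stim_start = baseline_duration,
                              onsets = onsets,
                              sampled_onsets = sampled_onsets,
                              amplitudes = amps, decay_tau = decay_tau,
                              rundown_fraction = rundown_fraction,
                              responder = responder,
                              baseline_F = baseline_F)),
            class = "synthetic_trace")
}

#' Generate a synthetic AChR cluster field with ground truth
#'
#' Scatters non-overlapping elliptical blobs (acetylcholine-receptor
#' clusters) over the field. The truth table records the exact rasterized
#' area of each blob, the quantity the area filter operates on.
#'
#' @param n_clusters number of blobs (>= 0).
#' @param areas optional explicit vector of target analytic areas in um^2
#'   (length `n_clusters`); otherwise areas are drawn log-normally with
#'   log-mean `log(area_meanlog)` and log-SD `area_sdlog`.
#' @param area_meanlog,area_sdlog lognormal area parameters (defaults:
#'   median 6 um^2, log-SD 0.6).
#' @param field_size image size in pixels `c(rows, cols)`.
#' @param pixel_size micrometres per pixel.
#' @param min_gap_um minimal border-to-border spacing between blobs, um.
#' @param seed integer RNG seed.
#' @param max_retries placement retries per blob.
#' @return List of class `achr_field`: `mask` (a [labeled_mask()]) and
#'   `truth` (data.frame `label`, `n_pixels`, `area_um2` rasterized,
#'   `target_area_um2`, `centroid_x_um`, `centroid_y_um`).
#' @export
generate_achr_field <- function(n_clusters, areas = NULL, area_meanlog = 6,
                                area_sdlog = 0.6,
                                field_size = c(400L, 400L),
                                pixel_size = 0.25, min_gap_um = 1,
                                seed = 1L, max_retries = 1000L) {
  stopifnot(n_clusters >= 0, pixel_size > 0)
  nr <- as.integer(field_size[1L]); nc <- as.integer(field_size[2L])
  labels <- matrix(0L, nr, nc)
  empty <- data.frame(label = integer(0), n_pixels = integer(0),
                      area_um2 = numeric(0), target_area_um2 = numeric(0),
                      centroid_x_um = numeric(0), centroid_y_um = numeric(0))
  if (n_clusters == 0L)
    return(structure(list(mask = labeled_mask(labels, pixel_size),
                          truth = empty), class = "achr_field"))
  withr::with_seed(seed, {
    if (is.null(areas))
      areas <- stats::rlnorm(n_clusters, log(area_meanlog), area_sdlog)
    stopifnot(length(areas) == n_clusters, all(areas > 0))
    ecc <- stats::runif(n_clusters, 0, 0.6)
    ori <- stats::runif(n_clusters, -90, 90)
    placed <- vector("list", n_clusters)
    rows <- vector("list", n_clusters)
    for (i in seq_len(n_clusters)) {
      a_um <- sqrt(areas[i] / (pi * sqrt(1 - ecc[i]^2)))
      b_um <- a_um * sqrt(1 - ecc[i]^2)
      a <- a_um / pixel_size; b <- b_um / pixel_size
      ok <- FALSE
      for (try in seq_len(max_retries)) {
        cr <- stats::runif(1, a + 2, nr - a - 1)
        cc <- stats::runif(1, a + 2, nc - a - 1)
        px <- rasterize_ellipse(cr, cc, a, b, ori[i], nr, nc)
        if (nrow(px) == 0L) next
        if (any(labels[px] != 0L)) next
        bd_um <- pixelset_boundary(px) * pixel_size
        clash <- FALSE
        for (j in seq_len(i - 1L))
          if (min_cross_distance(bd_um, placed[[j]]) < min_gap_um) {
            clash <- TRUE; break
          }
        if (clash) next
        labels[px] <- i
        placed[[i]] <- bd_um
        rows[[i]] <- data.frame(label = i, n_pixels = nrow(px),
                                area_um2 = nrow(px) * pixel_size^2,
                                target_area_um2 = areas[i],
                                centroid_x_um = (mean(px[, 2L]) - 1) *
                                  pixel_size,
                                centroid_y_um = (mean(px[, 1L]) - 1) *
                                  pixel_size)
        ok <- TRUE
        break
      }
      if (!ok) placement_error(sprintf("AChR cluster %d", i))
    }
    truth <- do.call(rbind, rows)
    rownames(truth) <- NULL
    structure(list(mask = labeled_mask(labels, pixel_size), truth = truth),
              class = "achr_field")
  })
}

#' Generate a synthetic sarcomere striation line profile
#'
#' A train of `n_periods` Gaussian intensity peaks spaced exactly `period`
#' micrometres apart (z-line striations along a line profile), sampled
#' uniformly every `sampling` micrometres, with optional additive Gaussian
#' noise. The noiseless profile has an exact peak-to-peak distance of
#' `period`.
#'
#' @param period peak spacing in um (> `peak_width`).
#' @param n_periods number of peaks (>= 3).
#' @param peak_width full width at half maximum of each peak, um.
#' @param noise_sd additive noise SD (intensity units; peaks have height 1).
#' @param sampling sample spacing in um; must be finer than `peak_width`.
#' @param seed integer RNG seed.
#' @return data.frame with `position_um` and `intensity`.
#' @export
generate_striation_profile <- function(period, n_periods, peak_width = 0.8,
                                       noise_sd = 0, sampling = 0.1,
                                       seed = 1L) {
  if (n_periods < 3) stop("`n_periods` must be >= 3")
  if (period <= peak_width) stop("`period` must exceed `peak_width`")
  if (sampling >= peak_width)
    stop("`sampling` must be finer than `peak_width`")
  total <- (n_periods + 1) * period
  pos <- seq(0, total, by = sampling)
  centers <- period * seq_len(n_periods)
  sd_um <- peak_width / (2 * sqrt(2 * log(2)))
  intensity <- rowSums(vapply(centers, function(c0)
    exp(-(pos - c0)^2 / (2 * sd_um^2)), numeric(length(pos))))
  intensity <- intensity + withr::with_seed(seed,
    stats::rnorm(length(pos), 0, noise_sd))
  data.frame(position_um = pos, intensity = intensity)
}

#' Generate a synthetic qPCR Ct table with ground truth
#'
#' Builds a gene-by-sample threshold-cycle matrix from per-condition true
#' fold changes relative to a reference condition:
#' `Ct = base_ct - log_eff(fold) + sample offset + noise`. Housekeeping
#' genes must have unit fold change in every condition (they are the
#' stability anchor of the geNorm normalization). A noiseless table inverts
#' exactly under [fold_change()].
#'
#' @param genes character vector of gene ids.
#' @param conditions character vector of condition names; must include
#'   `reference`.
#' @param replicates samples per condition.
#' @param true_fold_changes numeric matrix `genes x conditions` of fold
#'   changes relative to `reference` (reference column all 1).
#' @param hk_genes housekeeping genes (>= 2, subset of `genes`, unit fold).
#' @param reference the reference condition (e.g. adult tissue).
#' @param noise_sd per-measurement Ct noise SD in cycles.
#' @param sample_offset_sd SD of a per-sample global Ct shift (pipetting
#'   offset; absorbed by the normalization factor).
#' @param base_ct baseline Ct per gene in the reference condition
#'   (recycled).
#' @param efficiency amplification factor per cycle (> 1, default 2).
#' @param seed integer RNG seed.
#' @return List of class `synthetic_ct`: `table` (a [ct_table()]) and
#'   `truth` (the fold-change matrix).
#' @export
generate_ct_table <- function(genes, conditions, replicates = 3,
                              true_fold_changes, hk_genes, reference,
                              noise_sd = 0, sample_offset_sd = 0,
                              base_ct = 20, efficiency = 2, seed = 1L) {
  genes <- as.character(genes); conditions <- as.character(conditions)
  if (length(hk_genes) < 2L)
    stop("at least two housekeeping genes are required")
  if (!all(hk_genes %in% genes))
    stop("`hk_genes` must be a subset of `genes`")
  if (!reference %in% conditions)
    stop("`reference` must be one of `conditions`")
  true_fold_changes <- as.matrix(true_fold_changes)
  stopifnot(nrow(true_fold_changes) == length(genes),
            ncol(true_fold_changes) == length(conditions),
            all(true_fold_changes > 0))
  dimnames(true_fold_changes) <- list(genes, conditions)
  if (any(abs(true_fold_changes[hk_genes, ] - 1) > 1e-12))
    stop("housekeeping genes must have unit true fold change everywhere")
  if (any(abs(true_fold_changes[, reference] - 1) > 1e-12))
    stop("the reference condition must have unit fold change for all genes")
  base_ct <- rep_len(base_ct, length(genes))
  sample_cond <- rep(conditions, each = replicates)
  sample_ids <- paste0(sample_cond, "_r",
                       rep(seq_len(replicates), times = length(conditions)))
  withr::with_seed(seed, {
    offsets <- stats::rnorm(length(sample_ids), 0, sample_offset_sd)
    ct <- matrix(NA_real_, length(genes), length(sample_ids),
                 dimnames = list(genes, sample_ids))
    for (g in seq_along(genes)) for (s in seq_along(sample_ids)) {
      fold <- true_fold_changes[g, sample_cond[s]]
      ct[g, s] <- base_ct[g] - log(fold) / log(efficiency) + offsets[s] +
        stats::rnorm(1, 0, noise_sd)
    }
    tab <- ct_table(ct, conditions = sample_cond, hk_genes = hk_genes,
                    reference = reference, efficiency = efficiency)
    structure(list(table = tab, truth = true_fold_changes),
              class = "synthetic_ct")
  })
}
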