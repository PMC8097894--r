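#' Normalize a fluorescence trace to its pre-stimulus baseline (F/F0)
#'
#' F0 is the mean raw fluorescence over a baseline window preceding the
#' first burst onset (default: the 5 s immediately before stimulation
#' start). Normalizing an already-normalized trace with the same window is
#' the identity.
#'
#' @param time_s sample times in seconds, monotone increasing.
#' @param F raw fluorescence, one value per sample (a.u.).
#' @param stim_start time of the first burst onset, seconds.
#' @param baseline_window `c(from, to)` in seconds; must end at or before
#'   `stim_start` and contain at least 3 samples. Default
#'   `c(stim_start - 5, stim_start)`.
#' @return A `fluo_trace`: data.frame with `time_s`, `F`, `normalized`
#'   (= F/F0), and attributes `F0`, `stim_start`, `baseline_window`.
#' @export
normalize_trace <- function(time_s, F, stim_start,
                            baseline_window = c(stim_start - 5, stim_start)) {
  if (is.data.frame(time_s)) { F <- time_s$F; time_s <- time_s$time_s }
  stopifnot(length(time_s) == length(F), !is.unsorted(time_s))
  if (length(baseline_window) != 2L ||
      baseline_window[2L] > stim_start + 1e-9)
    stop("baseline window must precede the first burst onset")
  in_win <- time_s >= baseline_window[1L] - 1e-9 &
    time_s < baseline_window[2L] + 1e-9
  if (sum(in_win) < 3L)
    stop("baseline window must contain at least 3 samples")
  F0 <- mean(F[in_win])
  if (!is.finite(F0) || F0 <= 0) stop("baseline F0 must be positive")
  structure(data.frame(time_s = time_s, F = F, normalized = F / F0),
            F0 = F0, stim_start = stim_start,
            baseline_window = baseline_window,
            class = c("fluo_trace", "data.frame"))
}

#' Per-burst transient amplitudes
#'
#' For each burst onset `t_k` of the protocol, the amplitude is
#' `max(F/F0) - 1` over the search window
#' `[t_k, t_k + burst_duration + search_extra]` (the window extends past
#' the burst to capture the decay-delayed maximum at slow sampling), and
#' is clipped at 0 by default.
#'
#' @param trace a `fluo_trace` from [normalize_trace()].
#' @param protocol a [stim_protocol()].
#' @param stim_start first burst onset time (default: taken from the
#'   trace attribute).
#' @param search_extra seconds appended to each burst window (default 2).
#' @param clip clip negative amplitudes at 0 (default TRUE).
#' @return Numeric vector with one amplitude (dF/F0) per protocol burst;
#'   18 for the default protocol. Errors, listing the missing bursts, when
#'   the trace is shorter than the protocol.
#' @export
per_burst_peaks <- function(trace, protocol,
                            stim_start = attr(trace, "stim_start"),
                            search_extra = 2, clip = TRUE) {
  stopifnot(inherits(trace, "fluo_trace"), inherits(protocol, "stim_protocol"))
  onsets <- burst_onsets(protocol, stim_start)
  t_end <- max(trace$time_s)
  missing <- which(onsets > t_end + 1e-9)
  if (length(missing) > 0L)
    stop(sprintf("trace shorter than protocol: missing burst(s) %s",
                 paste(missing, collapse = ", ")))
  amps <- vapply(onsets, function(on) {
    win <- trace$time_s >= on - 1e-9 &
      trace$time_s <= on + protocol$burst_duration + search_extra + 1e-9
    max(trace$normalized[win]) - 1
  }, numeric(1))
  if (clip) amps <- pmax(amps, 0)
  amps
}

#' Responder classification
#'
#' A cell is a responder when the amplitude of its first
#' stimulation-evoked transient strictly exceeds the threshold
#' (default 0.5 dF/F0); an amplitude exactly at the threshold is a
#' non-responder.
#'
#' @param first_amplitude first-transient amplitude(s), dF/F0.
#' @param threshold classification threshold (default 0.5).
#' @return Logical vector.
#' @export
classify_responder <- function(first_amplitude, threshold = 0.5) {
  first_amplitude > threshold
}

#' Decay time of the first transient
#'
#' Default definition: the time from the first-transient peak to the first
#' crossing of `baseline + amplitude / e` (baseline = 1 in F/F0 units),
#' with linear interpolation between samples — for a monoexponential decay
#' this equals the time constant tau. A monoexponential fit of
#' `log(F/F0 - 1)` over the decay is available as `method = "fit"`. If the
#' trace never crosses the level before the next burst the value is
#' censored.
#'
#' @param trace a `fluo_trace`.
#' @param protocol a [stim_protocol()].
#' @param stim_start first burst onset (default from trace attribute).
#' @param search_extra peak search extension per burst, seconds.
#' @param method `"crossing"` (default) or `"fit"`.
#' @return List with `decay_s` (seconds; `NA` when censored), `censored`
#'   (logical), `method`, `peak_time_s`, `first_amplitude`. Errors (class
#'   `myoquant_undefined`) when the first amplitude is not positive.
#' @export
decay_time <- function(trace, protocol,
                       stim_start = attr(trace, "stim_start"),
                       search_extra = 2, method = c("crossing", "fit")) {
  method <- match.arg(method)
  stopifnot(inherits(trace, "fluo_trace"), inherits(protocol, "stim_protocol"))
  onsets <- burst_onsets(protocol, stim_start)
  win_end <- if (length(onsets) > 1L) onsets[2L] else max(trace$time_s)
  peak_win <- which(trace$time_s >= onsets[1L] - 1e-9 &
                    trace$time_s <= onsets[1L] + protocol$burst_duration +
                      search_extra + 1e-9)
  if (length(peak_win) == 0L) stop("trace does not cover the first burst")
  ipk <- peak_win[which.max(trace$normalized[peak_win])]
  amp <- trace$normalized[ipk] - 1
  if (amp <= 0)
    abort_undefined("decay time undefined: first amplitude is not positive")
  decay_idx <- which(trace$time_s >= trace$time_s[ipk] &
                     trace$time_s < win_end - 1e-9)
  tt <- trace$time_s[decay_idx]; vv <- trace$normalized[decay_idx]
  if (method == "fit") {
    usable <- vv - 1 > 0.02 * amp
    if (sum(usable) < 3L)
      return(list(decay_s = NA_real_, censored = TRUE, method = method,
                  peak_time_s = trace$time_s[ipk], first_amplitude = amp))
    fit <- stats::lm(log(vv[usable] - 1) ~ tt[usable])
    tau <- -1 / stats::coef(fit)[[2L]]
    return(list(decay_s = tau, censored = FALSE, method = method,
                peak_time_s = trace$time_s[ipk], first_amplitude = amp))
  }
  level <- 1 + amp * exp(-1)
  below <- which(vv <= level + 1e-12)
  below <- below[below > 1L]
  if (length(below) == 0L)
    return(list(decay_s = NA_real_, censored = TRUE, method = method,
                peak_time_s = trace$time_s[ipk], first_amplitude = amp))
  i <- below[1L]
  t_cross <- tt[i - 1L] + (vv[i - 1L] - level) / (vv[i - 1L] - vv[i]) *
    (tt[i] - tt[i - 1L])
  list(decay_s = t_cross - trace$time_s[ipk], censored = FALSE,
       method = method, peak_time_s = trace$time_s[ipk],
       first_amplitude = amp)
}

#' Percentage of remaining calcium
#'
#' Amplitude of the last burst-evoked transient as a percentage of the
#' first one; measures the run-down of the response over the stimulation.
#'
#' @param per_burst_amplitude amplitudes from [per_burst_peaks()].
#' @return `100 * last / first`. Errors (class `myoquant_undefined`) when
#'   the first amplitude is not positive.
#' @export
remaining_calcium <- function(per_burst_amplitude) {
  n <- length(per_burst_amplitude)
  if (n == 0L || per_burst_amplitude[1L] <= 0)
    abort_undefined("remaining calcium undefined: first amplitude not positive")
  100 * per_burst_amplitude[n] / per_burst_amplitude[1L]
}

#' All transient metrics of one cell
#'
#' Convenience wrapper running [per_burst_peaks()], [classify_responder()],
#' [decay_time()] and [remaining_calcium()] on a normalized trace.
#' Undefined remaining-calcium or decay values are reported as `NA` rather
#' than errors, so cohorts containing non-responding cells can be
#' summarized.
#'
#' @inheritParams per_burst_peaks
#' @param threshold responder threshold (default 0.5 dF/F0).
#' @param decay_method `"crossing"` or `"fit"` (see [decay_time()]).
#' @return List of class `transient_metrics`: `per_burst_amplitude`,
#'   `first_amplitude`, `is_responder`, `decay_s`, `decay_censored`,
#'   `remaining_pct`.
#' @export
transient_metrics <- function(trace, protocol,
                              stim_start = attr(trace, "stim_start"),
                              search_extra = 2, threshold = 0.5,
                              decay_method = "crossing") {
  amps <- per_burst_peaks(trace, protocol, stim_start, search_extra)
  first <- amps[1L]
  dec <- tryCatch(decay_time(trace, protocol, stim_start, search_extra,
                             method = decay_method),
                  myoquant_undefined = function(e)
                    list(decay_s = NA_real_, censored = NA))
  rem <- tryCatch(remaining_calcium(amps),
                  myoquant_undefined = function(e) NA_real_)
  structure(list(per_burst_amplitude = amps, first_amplitude = first,
                 is_responder = classify_responder(first, threshold),
                 decay_s = dec$decay_s, decay_censored = dec$censored,
                 remaining_pct = rem),
            class = "transient_metrics")
}

#' @export
print.transient_metrics <- function(x, ...) {
  cat(sprintf(paste0("<transient_metrics> first amplitude %.3f dF/F0 ",
                     "(%s) | decay %s s | remaining %s%% | %d bursts\n"),
              x$first_amplitude,
              if (isTRUE(x$is_responder)) "responder" else "non-responder",
              format(round(x$decay_s, 3)), format(round(x$remaining_pct, 1)),
              length(x$per_burst_amplitude)))
  invisible(x)
}

#' Responder rate per group
#'
#' @param is_responder logical vector, one flag per cell.
#' @param group group label per cell (e.g. flat vs nanopattern).
#' @return data.frame with `group`, `n`, `n_responders`, `rate`. Errors
#'   (class `myoquant_undefined`) on an empty input or a group with no
#'   cells.
#' @export
population_response_rates <- function(is_responder, group) {
  if (length(is_responder) == 0L)
    abort_undefined("response rate undefined: no cells")
  stopifnot(length(is_responder) == length(group))
  if (anyNA(is_responder)) stop("`is_responder` must not contain NA")
  group <- factor(group)
  if (any(table(group) == 0L))
    abort_undefined("response rate undefined for an empty group")
  n <- as.vector(table(group))
  pos <- as.vector(tapply(is_responder, group, sum))
  data.frame(group = levels(group), n = n, n_responders = pos,
             rate = pos / n)
}
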