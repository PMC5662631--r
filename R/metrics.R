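#' Detect spikes in a voltage trace
#'
#' Upward threshold crossings separated by at least the refractory period.
#'
#' @param trace numeric voltage trace (mV), sampled at `dt`.
#' @param dt sample interval (ms).
#' @param threshold crossing threshold (mV), default -20.
#' @param refractory lockout after a detected spike (ms), default 2.
#' @return numeric vector of spike times (ms, time of the crossing sample).
#' @export
detect_spikes <- function(trace, dt, threshold = -20, refractory = 2) {
  stopifnot(dt > 0)
  n <- length(trace)
  if (n < 2) return(numeric())
  up <- which(trace[-1] >= threshold & trace[-n] < threshold)
  if (!length(up)) return(numeric())
  times <- up * dt
  keep <- c(TRUE, rep(FALSE, length(times) - 1))
  last <- times[1]
  for (i in seq_along(times)[-1]) {
    if (times[i] - last >= refractory) {
      keep[i] <- TRUE
      last <- times[i]
    }
  }
  times[keep]
}

#' Classify thalamic response peaks
#'
#' Partitions the expected-response windows exhaustively and exclusively
#' into lost, incomplete and normal peaks. Candidate events are local
#' maxima of the trace above the detection floor (10% of the reference
#' maximum above baseline), merged when closer than `min_sep`; each window
#' is scored by its tallest event: at least 90% of the reference maximum
#' is a normal peak, between 10% and 90% an incomplete peak, and a window
#' with no event above the floor is a lost peak (the rest state).
#'
#' Windows default to the whole trace cut into `n_windows` equal bins;
#' supply window edges from a normal-state calibration run for relay
#' scoring (see [relay_reference()]).
#'
#' @param trace voltage trace (mV).
#' @param dt sample interval (ms).
#' @param baseline baseline voltage (mV) above which heights are measured.
#' @param ref_max reference maximum peak height (mV above baseline) from the
#'   healthy calibration; `NULL` uses the trace's own maximum.
#' @param windows numeric vector of window edges (ms), length >= 2; or
#'   `NULL` to use `n_windows` equal bins.
#' @param n_windows number of equal windows when `windows` is `NULL`.
#' @param min_sep minimum separation (ms) between distinct events.
#' @return tibble with `n_lost`, `n_incomplete`, `n_normal`, `peak_max`.
#' @export
classify_peaks <- function(trace, dt, baseline = -70, ref_max = NULL,
                           windows = NULL, n_windows = 10, min_sep = 5) {
  stopifnot(length(trace) >= 2, dt > 0)
  heights <- trace - baseline
  if (is.null(ref_max)) ref_max <- max(heights)
  if (!is.finite(ref_max) || ref_max <= 0) {
    stop("degenerate trace: reference maximum is not positive")
  }
  t <- (seq_along(trace) - 1) * dt
  if (is.null(windows)) {
    windows <- seq(0, t[length(t)], length.out = n_windows + 1)
  }
  stopifnot(length(windows) >= 2)
  n <- length(trace)
  floor_h <- 0.1 * ref_max
  is_peak <- c(FALSE, heights[2:(n - 1)] >= heights[1:(n - 2)] &
                 heights[2:(n - 1)] > heights[3:n], FALSE) &
    heights >= floor_h
  pk_t <- t[is_peak]
  pk_h <- heights[is_peak]
  if (length(pk_t)) {
    # merge maxima closer than min_sep into single events (keep the tallest)
    grp <- cumsum(c(1, diff(pk_t) > min_sep))
    pk_h <- vapply(split(pk_h, grp), max, numeric(1))
    pk_t <- vapply(split(pk_t, grp), function(x) x[1], numeric(1))
  }
  n_lost <- 0L; n_norm <- 0L; n_inc <- 0L
  for (w in seq_len(length(windows) - 1)) {
    lo <- windows[w]; hi <- windows[w + 1]
    sel <- pk_t >= lo & pk_t < hi
    if (!any(sel)) {
      n_lost <- n_lost + 1L
    } else if (max(pk_h[sel]) >= 0.9 * ref_max) {
      n_norm <- n_norm + 1L
    } else {
      n_inc <- n_inc + 1L
    }
  }
  tibble::tibble(n_lost = n_lost, n_incomplete = n_inc,
                 n_normal = n_norm, peak_max = ref_max)
}

#' Error index (EI)
#'
#' Relay-fidelity metric: the number of incomplete thalamic peaks divided
#' by the number of normal peaks.
#'
#' @param counts tibble or list with `n_incomplete` and `n_normal` (as from
#'   [classify_peaks()]), or a numeric `n_incomplete` when `n_normal` is
#'   given separately.
#' @param n_normal optional normal-peak count.
#' @return scalar EI.
#' @export
error_index <- function(counts, n_normal = NULL) {
  if (is.null(n_normal)) {
    n_inc <- counts$n_incomplete
    n_normal <- counts$n_normal
  } else {
    n_inc <- counts
  }
  if (any(n_normal <= 0)) {
    stop("EI is undefined: no normal peaks in the window set")
  }
  n_inc / n_normal
}

#' Mean firing rate
#'
#' @param spike_times numeric spike times (ms).
#' @param window observation window (ms) or `c(t0, t1)` interval.
#' @return rate in Hz.
#' @export
mean_firing_rate <- function(spike_times, window) {
  if (length(window) == 2) {
    n <- sum(spike_times >= window[1] & spike_times < window[2])
    span <- diff(window)
  } else {
    stopifnot(window > 0)
    n <- length(spike_times)
    span <- window
  }
  1000 * n / span
}

#' Mean spikes per burst
#'
#' Bursts are maximal runs of spikes whose inter-spike intervals do not
#' exceed `isi_gap`.
#'
#' @param spike_times numeric spike times (ms).
#' @param isi_gap burst-delimiting interval (ms), default 50.
#' @return mean number of spikes per burst (0 for an empty train).
#' @export
spikes_per_burst <- function(spike_times, isi_gap = 50) {
  stopifnot(isi_gap > 0)
  n <- length(spike_times)
  if (n == 0) return(0)
  if (n == 1) return(1)
  breaks <- diff(spike_times) > isi_gap
  burst_id <- cumsum(c(1, breaks))
  mean(tabulate(burst_id))
}

#' GPi-thalamic phase diagram
#'
#' Pairs the two voltage traces sample-by-sample and summarises the
#' dispersion of the thalamic potential conditioned on binned pallidal
#' potential -- the signature used to judge relay coherence (scattered
#' values above the -70 mV pallidal range indicate a degraded channel).
#'
#' @param gpi_trace,th_trace equal-length voltage traces (mV).
#' @param breaks GPi bin edges (mV) or a bin count.
#' @return list with `pairs` (tibble `v_gpi`, `v_th`) and `dispersion`
#'   (tibble `bin_lo`, `bin_hi`, `n`, `sd_th`).
#' @export
phase_diagram <- function(gpi_trace, th_trace, breaks = 20) {
  if (length(gpi_trace) != length(th_trace)) {
    stop("phase_diagram: traces must have equal length")
  }
  pairs <- tibble::tibble(v_gpi = as.numeric(gpi_trace),
                          v_th = as.numeric(th_trace))
  cuts <- if (length(breaks) == 1) {
    seq(min(pairs$v_gpi), max(pairs$v_gpi), length.out = breaks + 1)
  } else breaks
  bin <- cut(pairs$v_gpi, cuts, include.lowest = TRUE)
  disp <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(bin = bin, v_th = pairs$v_th), bin),
    n = dplyr::n(),
    sd_th = stats::sd(v_th),
    .groups = "drop"
  )
  lo <- cuts[-length(cuts)]; hi <- cuts[-1]
  disp$bin_lo <- lo[as.integer(disp$bin)]
  disp$bin_hi <- hi[as.integer(disp$bin)]
  disp$bin <- NULL
  structure(list(pairs = pairs,
                 dispersion = disp[, c("bin_lo", "bin_hi", "n", "sd_th")]),
            class = "bg_phase_diagram")
}

#' Relay reference from a healthy calibration recording
#'
#' Derives, from a normal-state thalamic trace, the reference maximum peak
#' height and the expected-response window grid (period = the median
#' inter-burst interval of the calibration run) used by [classify_peaks()]
#' when scoring lesioned/depleted conditions.
#'
#' @param trace calibration voltage trace (mV).
#' @param dt sample interval (ms).
#' @param baseline baseline voltage (mV).
#' @param isi_gap burst-delimiting gap (ms) for the window rhythm.
#' @param t_start discard transient before this time (ms).
#' @return list with `ref_max`, `period`, and a `windows` builder
#'   (function of total duration).
#' @export
relay_reference <- function(trace, dt, baseline = -70, isi_gap = 50,
                            t_start = 500) {
  t <- (seq_along(trace) - 1) * dt
  keep <- t >= t_start
  tr <- trace[keep]
  ref_max <- max(tr - baseline)
  sp <- detect_spikes(tr, dt)
  if (length(sp) >= 2) {
    bursts <- split(sp, cumsum(c(1, diff(sp) > isi_gap)))
    starts <- vapply(bursts, function(b) b[1], numeric(1))
    period <- if (length(starts) >= 2) stats::median(diff(starts)) else NA_real_
  } else {
    period <- NA_real_
  }
  if (!is.finite(period) || period <= 0) period <- 100
  list(
    ref_max = ref_max,
    period = period,
    windows = function(duration, t0 = t_start) seq(t0, duration, by = period)
  )
}
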