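#' Compute the local field potential proxy
#'
#' The LFP is the difference between the voltage at the most distal apical
#' dendrite (`Adend3`) and the basal dendrite (`Bdend`) of each pyramidal
#' neuron, averaged over all pyramidal neurons. It is linear in the
#' compartment voltages and rejects any common-mode offset.
#'
#' @param sim a `ca3_sim`, or a list/data frame with per-cell `adend3` and
#'   `bdend` voltage matrices (time x cells).
#' @param window analysis window `c(start, end)` in ms; defaults to the
#'   post-equilibration window of the run.
#' @return an `lfp_trace`: tibble with `time` (ms) and `value` (mV), sample
#'   rate in attribute `fs` (Hz).
#' @export
compute_lfp <- function(sim, window = NULL) {
  if (inherits(sim, "ca3_sim")) {
    if (is.null(window)) window <- c(sim$discard, sim$duration)
    t <- seq(0, sim$duration, by = sim$record_dt)
    if (!is.null(sim$voltages)) {
      npyr <- ncol(sim$voltages) / 2
      d <- sim$voltages[, seq_len(npyr), drop = FALSE] -
        sim$voltages[, npyr + seq_len(npyr), drop = FALSE]
      v <- rowMeans(d)
    } else {
      if (!length(sim$mean_adend3)) abort("no pyramidal voltage traces recorded")
      v <- sim$mean_adend3 - sim$mean_bdend
    }
    fs <- 1000 / sim$record_dt
  } else if (is.list(sim) && !is.null(sim$adend3) && !is.null(sim$bdend)) {
    if (!identical(dim(sim$adend3), dim(sim$bdend))) {
      abort("adend3 and bdend traces must have identical shape")
    }
    v <- rowMeans(sim$adend3 - sim$bdend)
    fs <- sim$fs %||% 1000
    t <- seq_along(v) / fs * 1000 - 1000 / fs
    if (is.null(window)) window <- range(t)
  } else {
    abort("compute_lfp needs a ca3_sim or adend3/bdend matrices")
  }
  keep <- t >= window[1] & t <= window[2]
  structure(tibble(time = t[keep], value = v[keep]),
            fs = fs, window = window,
            class = c("lfp_trace", class(tibble())))
}

#' Welch power spectral density
#'
#' Standard Welch estimate: the series is split into Hann-windowed segments
#' with the given overlap, each segment mean-removed, and one-sided
#' periodograms (density scaling, power per Hz) are averaged.
#'
#' @param x numeric series, or an `lfp_trace`.
#' @param fs sample rate (Hz); taken from the trace when `x` is one.
#' @param segment_len segment length in seconds.
#' @param overlap fractional overlap between segments.
#' @return a `psd` tibble with columns `frequency` (Hz) and `power`.
#' @export
welch_power <- function(x, fs = NULL, segment_len = 1, overlap = 0.5) {
  if (inherits(x, "lfp_trace")) {
    fs <- attr(x, "fs")
    x <- x$value
  }
  if (is.null(fs)) abort("fs is required")
  nseg <- round(segment_len * fs)
  if (length(x) < nseg) abort("trace shorter than one Welch segment")
  step <- max(1, round(nseg * (1 - overlap)))
  starts <- seq(1, length(x) - nseg + 1, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, nseg - 1) / nseg)  # periodic Hann
  scale <- fs * sum(w^2)
  nfreq <- nseg %/% 2 + 1
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- x[s:(s + nseg - 1)]
    seg <- (seg - mean(seg)) * w
    p <- abs(fft(seg)[seq_len(nfreq)])^2 / scale
    # one-sided: double everything except DC (and Nyquist for even nseg)
    p[2:(nfreq - 1)] <- 2 * p[2:(nfreq - 1)]
    if (nseg %% 2 == 1) p[nfreq] <- 2 * p[nfreq]
    acc <- acc + p
  }
  structure(tibble(frequency = seq(0, nfreq - 1) * fs / nseg,
                   power = acc / length(starts)),
            fs = fs, class = c("psd", class(tibble())))
}

#' Summed band power
#'
#' Sum of Welch power values over frequency bins with `lo <= f <= hi`.
#' The gamma band is 30-100 Hz.
#'
#' @param spec a `psd` tibble from [welch_power()].
#' @param lo,hi band edges (Hz).
#' @export
band_power <- function(spec, lo = 30, hi = 100) {
  stopifnot(is.data.frame(spec), all(c("frequency", "power") %in% names(spec)))
  sel <- spec$frequency >= lo & spec$frequency <= hi
  if (!any(sel)) abort("empty frequency band")
  sum(spec$power[sel])
}

#' Dominant spectral frequency
#'
#' Frequency of maximum Welch power, optionally restricted to a band.
#' @param spec a `psd` tibble.
#' @param lo,hi search band (Hz); default excludes the DC bin.
#' @export
peak_frequency <- function(spec, lo = 1, hi = Inf) {
  sel <- which(spec$frequency >= lo & spec$frequency <= hi)
  spec$frequency[sel[which.max(spec$power[sel])]]
}

#' Relative change in gamma power
#'
#' `delta_gamma = gamma_cond / gamma_ctrl - 1`: 0 for equal power, 1 for a
#' doubling, -0.5 for a halving. Bounded below by -1.
#'
#' @param gamma_cond,gamma_ctrl summed gamma band power of the scaled
#'   condition and its seed-matched control.
#' @export
delta_gamma <- function(gamma_cond, gamma_ctrl) {
  if (any(gamma_ctrl <= 0)) abort("control gamma power must be positive")
  gamma_cond / gamma_ctrl - 1
}

#' Gamma power of the pooled spike raster
#'
#' All spike times are pooled into one vector, binned at 1 ms, smoothed with
#' a 5 ms boxcar kernel (normalized to unit area), and the gamma band power
#' of the resulting population-rate signal is computed exactly as for the
#' LFP. Invariant to cell relabeling.
#'
#' @param spikes tibble with a `time` column (ms), or a `ca3_sim`.
#' @param window analysis window `c(start, end)` ms.
#' @param kernel_width boxcar width (ms).
#' @param bin bin width (ms).
#' @param lo,hi gamma band (Hz).
#' @param segment_len,overlap Welch parameters.
#' @return scalar gamma band power (0 for an empty raster).
#' @export
raster_gamma <- function(spikes, window, kernel_width = 5, bin = 1,
                         lo = 30, hi = 100, segment_len = 1, overlap = 0.5) {
  if (inherits(spikes, "ca3_sim")) {
    if (missing(window)) window <- c(spikes$discard, spikes$duration)
    spikes <- spikes$spikes
  }
  sig <- raster_signal(spikes, window, kernel_width, bin)
  if (is.null(sig)) return(0)
  band_power(welch_power(sig$value, fs = 1000 / bin,
                         segment_len = segment_len, overlap = overlap),
             lo, hi)
}

# pooled, boxcar-smoothed population rate signal on a regular grid
raster_signal <- function(spikes, window, kernel_width = 5, bin = 1) {
  t <- spikes$time[spikes$time >= window[1] & spikes$time < window[2]]
  if (!length(t)) return(NULL)
  edges <- seq(window[1], window[2], by = bin)
  counts <- tabulate(findInterval(t, edges), nbins = length(edges) - 1)
  k <- rep(1 / (kernel_width / bin), kernel_width / bin)
  sm <- stats::filter(counts, k, sides = 2)
  sm[is.na(sm)] <- 0
  tibble(time = edges[-length(edges)] + bin / 2, value = as.numeric(sm))
}

#' Mean population firing rate
#'
#' Spikes in the window divided by (number of cells x window length).
#'
#' @param sim a `ca3_sim` (or a spikes tibble with a `population` column).
#' @param population population label (`"pyr"`, `"olm"`, `"bas"`).
#' @param window analysis window (ms); defaults to post-equilibration.
#' @param n_cells required if `sim` is a bare tibble.
#' @return rate in Hz.
#' @export
mean_rate <- function(sim, population = "pyr", window = NULL, n_cells = NULL) {
  if (inherits(sim, "ca3_sim")) {
    if (is.null(window)) window <- c(sim$discard, sim$duration)
    n_cells <- sim$populations[[population]]
    spikes <- sim$spikes
  } else {
    spikes <- sim
    if (is.null(n_cells)) abort("n_cells required for a bare spikes table")
    if (is.null(window)) abort("window required for a bare spikes table")
  }
  if (!population %in% c(unique(spikes$population), "pyr", "olm", "bas")) {
    abort(paste0("unknown population: ", population))
  }
  n <- sum(spikes$population == population &
             spikes$time >= window[1] & spikes$time < window[2])
  n / n_cells / ((window[2] - window[1]) / 1000)
}
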