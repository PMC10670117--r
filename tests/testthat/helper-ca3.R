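# Shared helpers: small configurations and summary statistics used across
# the suite. Simulation-backed tests use the 80/20/20 desk-scale network for
# plumbing contracts and the full-size network (short recordings) where the
# oscillatory regime itself is under test.

tiny_cfg <- function(seed = 2L, ...) tiny_network_config(0.1, seed = seed, ...)

# gamma band power of an LFP trace / simulation, with the package defaults
lfp_gamma <- function(sim) band_power(welch_power(compute_lfp(sim)))

# theta rhythmicity score: autocorrelation of the pooled 5 ms-binned raster
# at the pacemaker period minus the off-period maximum
theta_strength <- function(spikes, win, period = 150) {
  sig <- ca3gamma:::raster_signal(spikes, win, kernel_width = 5, bin = 5)
  a <- stats::acf(sig$value, lag.max = ceiling(1.4 * period / 5),
                  plot = FALSE)$acf[, 1, 1]
  lags <- (seq_along(a) - 1) * 5
  max(a[abs(lags - period) <= 25]) - max(a[lags >= 45 & lags <= 97])
}

# settled resting potential of an isolated cell
settled_rest <- function(type, cfg = NULL, ms = 500) {
  tr <- simulate_cell(type, cfg, duration = ms)
  tail(tr$soma, 1)
}
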