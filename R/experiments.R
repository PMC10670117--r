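# Experiment protocols: the (krec, kext) scaling grid, the extended krec
# sweep with seizure detection, the delay sweep, and the single-cell
# voltage probe.

condition_metrics <- function(sim, ctrl_gamma = NULL) {
  lfp <- compute_lfp(sim)
  g <- band_power(welch_power(lfp))
  tibble(
    lfp_gamma = g,
    raster_gamma = raster_gamma(sim),
    delta_gamma = if (is.null(ctrl_gamma)) NA_real_ else delta_gamma(g, ctrl_gamma),
    pyr_rate = mean_rate(sim, "pyr")
  )
}

#' Run the (krec, kext) scaling grid
#'
#' One 7 s simulation per (krec, kext, seed) triple, each compared with the
#' seed-matched control (krec = kext = 1) sharing wiring, background event
#' streams and initial conditions. The control condition is always included
#' (with `delta_gamma = 0` exactly).
#'
#' @param config template configuration (its seed is overridden per run).
#' @param levels scaling levels for both factors.
#' @param seeds integer seeds, one control + grid per seed.
#' @param duration,discard run length / equilibration (ms).
#' @param verbose print one line per run.
#' @return tibble with one row per (krec, kext, seed): `lfp_gamma`,
#'   `raster_gamma`, `delta_gamma`, `pyr_rate`. Failed runs are dropped with
#'   a warning naming the condition.
#' @export
run_grid <- function(config, levels = c(1, 1.25, 1.5, 1.75), seeds = 1:16,
                     duration = 7000, discard = 3000, verbose = FALSE) {
  grid <- expand.grid(krec = levels, kext = levels)
  rows <- list()
  for (seed in seeds) {
    cfg <- config
    cfg$seed <- as.integer(seed)
    ctrl <- run_simulation(cfg, duration, discard)
    ctrl_gamma <- band_power(welch_power(compute_lfp(ctrl)))
    for (i in seq_len(nrow(grid))) {
      kr <- grid$krec[i]; ke <- grid$kext[i]
      res <- tryCatch({
        sim <- if (kr == 1 && ke == 1) ctrl else {
          run_simulation(apply_scaling(cfg, krec = kr, kext = ke),
                         duration, discard)
        }
        m <- condition_metrics(sim, ctrl_gamma)
        dplyr::bind_cols(tibble(krec = kr, kext = ke, seed = seed), m)
      }, error = function(e) {
        warning(sprintf("run (krec=%g, kext=%g, seed=%d) failed: %s",
                        kr, ke, seed, conditionMessage(e)), call. = FALSE)
        NULL
      })
      if (!is.null(res)) rows[[length(rows) + 1L]] <- res
      if (verbose && !is.null(res)) {
        message(sprintf("krec=%g kext=%g seed=%d  dG=%+.3f rate=%.2f Hz",
                        kr, ke, seed, res$delta_gamma, res$pyr_rate))
      }
    }
  }
  dplyr::bind_rows(rows)
}

# theta rhythmicity of the pooled raster: autocorrelation of binned counts
# shows a peak near the pacemaker period
has_theta_peak <- function(spikes, window, period = 150, bin = 5,
                           margin = 25, excess = 0.05) {
  sig <- raster_signal(spikes, window, kernel_width = bin, bin = bin)
  if (is.null(sig) || sd(sig$value) == 0) return(FALSE)
  a <- stats::acf(sig$value, lag.max = ceiling(1.4 * period / bin),
                  plot = FALSE)$acf[, 1, 1]
  lags <- (seq_along(a) - 1) * bin
  at_period <- max(a[abs(lags - period) <= margin])
  off <- a[lags >= 0.3 * period & lags <= 0.65 * period]
  at_period > max(off) + excess
}

# Seizure call for one scaled run against its seed-matched control: very
# high pyramidal rates or loss of the pacemaker's theta structure.
classify_seizure <- function(sim, ctrl_rate, rate_factor = 20) {
  rate <- mean_rate(sim, "pyr")
  epileptic <- (ctrl_rate > 0 && rate > rate_factor * ctrl_rate) ||
    !has_theta_peak(sim$spikes, c(sim$discard, sim$duration),
                    period = sim$config$ms$period)
  list(is_epileptic = epileptic, pyr_rate = rate)
}

#' Extended krec sweep with seizure detection
#'
#' Runs recurrent-only scaling at the requested (possibly far beyond
#' plausible) levels and flags the epileptic regime. A level is called
#' epileptic when the mean pyramidal rate exceeds `rate_factor` times the
#' seed-matched baseline or the pooled raster loses its theta periodicity;
#' since the transition is an abrupt phase change, verdicts are closed
#' upward (every level above an epileptic one is epileptic).
#'
#' @inheritParams run_grid
#' @param levels ascending krec levels (include 1 for the baseline).
#' @param rate_factor seizure threshold on the rate ratio.
#' @return list with `runs` (per run metrics + `is_epileptic`) and
#'   `verdicts` (per level: `is_epileptic`, mean `pyr_rate`).
#' @export
krec_sweep <- function(config, levels = c(1, 5, 10, 20, 37), seeds = 1:4,
                       duration = 7000, discard = 3000,
                       rate_factor = NULL) {
  stopifnot(!is.unsorted(levels))
  rate_factor <- rate_factor %||% config$seizure_rate_factor
  rows <- list()
  for (seed in seeds) {
    cfg <- config
    cfg$seed <- as.integer(seed)
    ctrl <- run_simulation(cfg, duration, discard)
    ctrl_gamma <- band_power(welch_power(compute_lfp(ctrl)))
    ctrl_rate <- mean_rate(ctrl, "pyr")
    for (kr in levels) {
      sim <- if (kr == 1) ctrl else {
        run_simulation(apply_scaling(cfg, krec = kr), duration, discard)
      }
      m <- condition_metrics(sim, ctrl_gamma)
      sz <- classify_seizure(sim, ctrl_rate, rate_factor)
      rows[[length(rows) + 1L]] <- dplyr::bind_cols(
        tibble(krec = kr, seed = seed), m,
        tibble(is_epileptic = sz$is_epileptic)
      )
    }
  }
  runs <- dplyr::bind_rows(rows)
  verdicts <- dplyr::summarise(
    dplyr::group_by(runs, .data$krec),
    pyr_rate = mean(.data$pyr_rate),
    is_epileptic = mean(.data$is_epileptic) > 0.5,
    .groups = "drop"
  )
  verdicts$is_epileptic <- cumsum(verdicts$is_epileptic) > 0  # upward closure
  list(runs = runs, verdicts = verdicts)
}

#' Delay sweep: gamma-krec slope vs added recurrent delay
#'
#' For each added recurrent synaptic delay, simulates the krec levels,
#' averages LFP gamma power over seeds, and fits the least-squares slope of
#' mean gamma against krec over the non-epileptic range. The slope's sign
#' alternates with delay at roughly the gamma period.
#'
#' @inheritParams run_grid
#' @param delays added recurrent delays (ms), on top of the universal 2 ms.
#' @param krec_levels krec levels used for each slope fit.
#' @return list with `slopes` (tibble delay, slope) and `runs`.
#' @export
delay_sweep <- function(config, delays = c(0, 17, 34, 51),
                        krec_levels = c(1, 5, 10, 20), seeds = 1:8,
                        duration = 7000, discard = 3000) {
  rows <- list()
  for (d in delays) {
    for (seed in seeds) {
      cfg <- config
      cfg$seed <- as.integer(seed)
      cfg$added_rec_delay <- d
      ctrl <- run_simulation(cfg, duration, discard)
      ctrl_rate <- mean_rate(ctrl, "pyr")
      ctrl_gamma <- band_power(welch_power(compute_lfp(ctrl)))
      for (kr in krec_levels) {
        sim <- if (kr == 1) ctrl else {
          run_simulation(apply_scaling(cfg, krec = kr), duration, discard)
        }
        m <- condition_metrics(sim, ctrl_gamma)
        sz <- classify_seizure(sim, ctrl_rate, config$seizure_rate_factor)
        rows[[length(rows) + 1L]] <- dplyr::bind_cols(
          tibble(delay = d, krec = kr, seed = seed), m,
          tibble(is_epileptic = sz$is_epileptic)
        )
      }
    }
  }
  runs <- dplyr::bind_rows(rows)
  ok <- dplyr::filter(runs, !.data$is_epileptic)
  means <- dplyr::summarise(dplyr::group_by(ok, .data$delay, .data$krec),
                            gamma = mean(.data$lfp_gamma), .groups = "drop")
  slopes <- dplyr::summarise(
    dplyr::group_by(means, .data$delay),
    slope = coef(lm(gamma ~ krec, data = dplyr::pick(dplyr::everything())))[2],
    .groups = "drop"
  )
  list(slopes = slopes, runs = runs)
}

#' Voltage probe: somatic response to a synchronized recurrent volley
#'
#' Reproduces the mechanism probe: all inputs to the pyramidal cell are
#' silenced, recurrent AMPA conductances are reduced to 10% of baseline, and
#' a single synchronized presynaptic volley (one spike per recurrent
#' synapse) is delivered to the basal-dendrite AMPA receptors at t = 0. The
#' somatic voltage is recorded from `-t_pre` to `t_post` ms around the
#' volley. The synaptic transmission delay is not included.
#'
#' @param config a `ca3_config`.
#' @param frac fraction of the baseline recurrent conductance used.
#' @param t_pre,t_post window around the volley (ms).
#' @param settle equilibration time simulated before the window (ms).
#' @return tibble with `time` (ms, volley at 0) and `voltage` (mV).
#' @export
voltage_probe <- function(config = NULL, frac = 0.1, t_pre = 20, t_post = 40,
                          settle = 300) {
  if (is.null(config)) config <- default_network_config()
  syn <- config$synapses
  row <- syn[syn$pre == "pyr" & syn$post == "pyr" & syn$receptor == "AMPA", ]
  conv <- config$convergence$n[config$convergence$pre == "pyr" &
                                 config$convergence$post == "pyr"]
  w <- conv * row$g * frac
  events <- tibble(time = settle + t_pre, comp = row$target, tau1 = row$tau1,
                   tau2 = row$tau2, erev = row$erev, weight = w)
  tr <- simulate_cell("pyr", config, duration = settle + t_pre + t_post,
                      events = events)
  keep <- tr$time >= settle
  tibble(time = tr$time[keep] - settle - t_pre, voltage = tr$soma[keep])
}
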