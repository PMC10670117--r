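#' Default CA3 network configuration
#'
#' Builds the full parameterization of the CA3 microcircuit: 800 pyramidal
#' cells (5 compartments: soma, basal dendrite `Bdend`, apical dendrites
#' `Adend1`-`Adend3`), 200 OLM and 200 basket interneurons (somata only), the
#' synapse table (kinetics and peak conductances per connection), background
#' Poisson drives, the medial-septum theta pacemaker (150 ms period), random
#' connectivity by convergence numbers, and the `krec`/`kext` AMPA scaling
#' condition.
#'
#' Recurrent pyramidal AMPA/NMDA synapses target the basal dendrite; OLM
#' inhibition targets the second apical compartment; all other connections
#' target somata. `krec` multiplies the recurrent pyramidal-to-pyramidal AMPA
#' conductance; `kext` multiplies the external (background) AMPA conductance
#' at the pyramidal soma and distal apical dendrite. The control condition is
#' `krec = kext = 1`.
#'
#' @param seed integer master seed; wiring, background event streams and
#'   initial-condition jitter are all derived from it, so two runs with the
#'   same seed (and config) are bit-identical.
#' @param krec,kext multiplicative AMPA scaling factors (>= 0; values > 1
#'   model post-ketamine potentiation).
#' @param added_rec_delay extra synaptic delay (ms) applied to recurrent
#'   pyramidal-to-pyramidal connections on top of the universal 2 ms.
#' @param scale population scale factor in (0, 1]; `scale = 0.1` gives the
#'   80/20/20 desk-size network with proportionally reduced convergence.
#' @return an object of class `ca3_config` (a named list; see Details).
#' @export
default_network_config <- function(seed = 1L, krec = 1, kext = 1,
                                   added_rec_delay = 0, scale = 1) {
  stopifnot(krec >= 0, kext >= 0, added_rec_delay >= 0, scale > 0, scale <= 1)
  pops <- as.integer(round(c(pyr = 800, olm = 200, bas = 200) * scale))
  names(pops) <- c("pyr", "olm", "bas")

  geometry <- list(
    pyr = data.frame(
      comp = c("soma", "Bdend", "Adend1", "Adend2", "Adend3"),
      L_um = c(20, 200, 150, 150, 150),
      diam_um = c(20, 2.5, 2.5, 2.5, 2.5)
    ),
    olm = data.frame(comp = "soma", L_um = 20, diam_um = 20),
    bas = data.frame(comp = "soma", L_um = 20, diam_um = 20)
  )

  # synapse table between populations (kinetics in ms, peak conductance nS)
  synapses <- tibble(
    pre = c("pyr", "pyr", "pyr", "pyr", "pyr", "pyr", "bas", "bas", "olm"),
    post = c("pyr", "pyr", "bas", "bas", "olm", "olm", "pyr", "bas", "pyr"),
    receptor = c("AMPA", "NMDA", "AMPA", "NMDA", "AMPA", "NMDA",
                 "GABAA", "GABAA", "GABAA"),
    target = c("Bdend", "Bdend", "soma", "soma", "soma", "soma",
               "soma", "soma", "Adend2"),
    tau1 = c(0.05, 15, 0.05, 15, 0.05, 15, 0.07, 0.07, 0.2),
    tau2 = c(5.3, 150, 5.3, 150, 5.3, 150, 9.1, 9.1, 20),
    g = c(0.02, 0.004, 0.36, 1.38, 0.36, 0.7, 0.72, 4.5, 72),
    erev = c(0, 0, 0, 0, 0, 0, -80, -80, -80),
    delay = 2
  )

  # background Poisson drives (per-cell independent streams)
  drives <- tibble(
    cell = c("pyr", "pyr", "pyr", "pyr", "pyr", "bas", "bas", "olm", "olm"),
    section = c("soma", "soma", "Adend3", "Adend3", "Adend3",
                "soma", "soma", "soma", "soma"),
    receptor = c("AMPA", "GABAA", "AMPA", "NMDA", "GABAA",
                 "AMPA", "GABAA", "AMPA", "GABAA"),
    rate = c(1000, 1000, 1000, 10, 1000, 1000, 1000, 1000, 1000),
    tau1 = c(0.05, 0.07, 0.05, 15, 0.07, 0.05, 0.07, 0.05, 0.07),
    tau2 = c(5.3, 9.1, 5.3, 150, 9.1, 5.3, 9.1, 5.3, 9.1),
    g = c(0.05, 0.012, 0.05, 6.5, 0.012, 0.02, 0.2, 0.0625, 0.2),
    erev = c(0, -80, 0, 0, -80, 0, -80, 0, -80)
  )

  # convergence numbers (randomly picked presynaptic partners per target);
  # not printed in the source material: free parameters of this
  # implementation, calibrated once to the baseline theta-nested-gamma
  # regime (33 Hz spectral peak, sparse pyramidal firing)
  convergence <- tibble(
    pre = c("pyr", "pyr", "pyr", "bas", "bas", "olm"),
    post = c("pyr", "bas", "olm", "pyr", "bas", "pyr"),
    n = pmax(1L, round(c(15, 100, 10, 50, 100, 10) * scale))
  )

  cfg <- structure(list(
    populations = pops,
    geometry = geometry,
    axial_resistivity = 100,   # ohm cm
    cm = 1,                    # uF/cm2
    channels = default_channels(),
    synapses = synapses,
    drives = drives,
    convergence = convergence,
    ms = list(period = 150, tau1 = 20, tau2 = 40, g = 1.6, erev = -80),
    ca = list(rest = 5e-5, tau = 200, influx = 0.01),  # mM, ms, mM cm2/(mA ms)
    # Jahr-Stevens voltage-dependent Mg2+ block on NMDA conductances
    nmda_mg = list(enabled = TRUE, eta = 0.28, gamma = 0.062),
    # tonic somatic drive (nA) per population, as in the predecessor-style
    # interneuron parameterization
    tonic = c(pyr = 0.18, olm = 0.05, bas = 0.30),
    scaling = c(krec = 1, kext = 1),
    added_rec_delay = added_rec_delay,
    dt = 0.025,
    record_dt = 1,
    v_rest = c(pyr = -67, olm = -66, bas = -67),
    init_jitter = 2,
    spike_threshold = 0,
    refractory = 3,
    seizure_rate_factor = 20,
    seed = as.integer(seed)
  ), class = "ca3_config")
  apply_scaling(cfg, krec = krec, kext = kext)
}

#' Desk-scale network configuration
#'
#' Scales population sizes and convergence numbers down proportionally while
#' keeping every kinetic parameter unchanged, for tests and CI-speed
#' experiment profiles. `scale = 0.1` gives 80/20/20 cells.
#'
#' @inheritParams default_network_config
#' @export
tiny_network_config <- function(scale = 0.1, seed = 1L, krec = 1, kext = 1,
                                added_rec_delay = 0) {
  cfg <- default_network_config(seed = seed, krec = krec, kext = kext,
                                added_rec_delay = added_rec_delay,
                                scale = scale)
  # 1/N compensation: convergence numbers shrink with the population, so each
  # network synapse is strengthened to preserve the mean synaptic conductance
  # per target cell (background drives are per-cell and stay unchanged)
  cfg$synapses$g <- cfg$synapses$g / scale
  bad <- cfg$convergence$n >= cfg$populations[cfg$convergence$pre]
  if (any(bad)) {
    abort("infeasible convergence after scaling: pool smaller than in-degree")
  }
  cfg
}

#' Apply the krec/kext AMPA scaling condition
#'
#' Pure transformation of a configuration: multiplies the recurrent
#' pyramidal-to-pyramidal AMPA peak conductance by `krec`, and the external
#' (background) AMPA conductance at the pyramidal soma and distal apical
#' dendrite by `kext`. NMDA, GABAA and interneuron drives are unchanged.
#' Scaling is multiplicative-compositional: scaling by `k` then `k'` equals
#' scaling by `k * k'`.
#'
#' @param config a `ca3_config`.
#' @param krec,kext scaling factors (>= 0).
#' @return a new `ca3_config`; the input is not modified.
#' @export
apply_scaling <- function(config, krec = 1, kext = 1) {
  stopifnot(inherits(config, "ca3_config"))
  if (krec < 0 || kext < 0) abort("scaling factors must be >= 0")
  syn <- config$synapses
  rec <- syn$pre == "pyr" & syn$post == "pyr" & syn$receptor == "AMPA"
  syn$g[rec] <- syn$g[rec] * krec
  drv <- config$drives
  ext <- drv$cell == "pyr" & drv$receptor == "AMPA" &
    drv$section %in% c("soma", "Adend1", "Adend2", "Adend3")
  drv$g[ext] <- drv$g[ext] * kext
  config$synapses <- syn
  config$drives <- drv
  config$scaling <- c(krec = unname(config$scaling["krec"] * krec),
                      kext = unname(config$scaling["kext"] * kext))
  config
}

#' @export
print.ca3_config <- function(x, ...) {
  cat("<ca3_config>\n")
  cat("  populations:", paste(names(x$populations), x$populations,
                              sep = "=", collapse = ", "), "\n")
  cat("  scaling: krec =", x$scaling["krec"], ", kext =", x$scaling["kext"], "\n")
  cat("  added recurrent delay:", x$added_rec_delay, "ms; dt:", x$dt, "ms\n")
  cat("  seed:", x$seed, "\n")
  invisible(x)
}

# compartment areas (cm2) for one cell type
comp_areas_cm2 <- function(geom) {
  pi * geom$diam_um * geom$L_um * 1e-8
}

# axial conductance (nS) between adjacent compartments, series half-cylinders
axial_g_nS <- function(geom, Ra, i, j) {
  half_r <- function(k) {
    Ra * (geom$L_um[k] * 1e-4 / 2) / (pi * (geom$diam_um[k] * 1e-4 / 2)^2)
  }
  1e9 / (half_r(i) + half_r(j))
}
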