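# Network assembly: translate a ca3_config into the flat arrays the C++
# integrator consumes. Compartments are numbered globally (0-based for C++):
# cells in population order pyr, olm, bas; within a pyramidal cell the local
# order is soma, Bdend, Adend1, Adend2, Adend3.

TYPE_ORDER <- c("pyr", "olm", "bas")
VGRID <- seq(-120, 60, by = 0.1)

build_network <- function(config) {
  pops <- config$populations[TYPE_ORDER]
  ncell <- sum(pops)
  cell_type <- rep(TYPE_ORDER, pops)
  pop_offset <- c(0L, cumsum(pops)[-3])
  names(pop_offset) <- TYPE_ORDER

  geom <- config$geometry
  ncomp_type <- vapply(geom[TYPE_ORDER], nrow, integer(1))
  comp_n <- ncomp_type[cell_type]
  comp_base <- cumsum(c(0L, comp_n[-ncell]))  # 0-based first comp per cell
  ncomp <- sum(comp_n)

  areas <- lapply(geom, comp_areas_cm2)
  cap_nF <- numeric(ncomp)
  for (ty in TYPE_ORDER) {
    cells <- which(cell_type == ty)
    for (k in seq_len(ncomp_type[ty])) {
      cap_nF[comp_base[cells] + k] <- config$cm * areas[[ty]][k] * 1e3
    }
  }

  # axial coupling (only pyramidal cells have > 1 compartment)
  ax_i <- integer(0); ax_j <- integer(0); ax_g <- numeric(0)
  for (ty in TYPE_ORDER) {
    g_ty <- geom[[ty]]
    if (nrow(g_ty) < 2) next
    # chain: Bdend - soma - Adend1 - Adend2 - Adend3
    pairs <- rbind(c(2, 1), c(1, 3), c(3, 4), c(4, 5))
    cells <- which(cell_type == ty)
    for (p in seq_len(nrow(pairs))) {
      gax <- axial_g_nS(g_ty, config$axial_resistivity, pairs[p, 1], pairs[p, 2])
      ax_i <- c(ax_i, comp_base[cells] + pairs[p, 1] - 1L)
      ax_j <- c(ax_j, comp_base[cells] + pairs[p, 2] - 1L)
      ax_g <- c(ax_g, rep(gax, length(cells)))
    }
  }

  # channels: one table-driven channel object per (cell type, channel)
  channels <- list()
  for (ty in TYPE_ORDER) {
    cells <- which(cell_type == ty)
    cn <- geom[[ty]]$comp
    for (ch in config$channels[[ty]]) {
      gd <- ch$g[cn]
      use <- which(!is.na(gd) & gd > 0)
      if (!length(use)) next
      comps0 <- as.integer(outer(comp_base[cells], use - 1L, `+`))
      gbar <- rep(gd[use] * areas[[ty]][use] * 1e9, each = length(cells))
      channels[[length(channels) + 1L]] <-
        channel_tables(ch, comps0, gbar, VGRID, config$dt)
    }
  }

  # Ca pools: compartments carrying a ca_source channel
  ca_comps <- integer(0); ca_area <- numeric(0)
  for (ch in channels) {
    if (ch$ca_source) {
      ca_comps <- c(ca_comps, ch$comps)
      ca_area <- c(ca_area, ch$gbar * 0)  # placeholder, filled below
    }
  }
  if (length(ca_comps)) {
    # recover areas from capacitance (cap_nF = cm * area_cm2 * 1e3)
    ca_area <- cap_nF[ca_comps + 1L] / (config$cm * 1e3)
  }

  # lumped synapse slots per cell type: unique (compartment, kinetics, erev)
  mg_on <- isTRUE(config$nmda_mg$enabled)
  req <- dplyr::distinct(dplyr::bind_rows(
    dplyr::transmute(config$synapses, type = .data$post, comp = .data$target,
                     tau1 = .data$tau1, tau2 = .data$tau2, erev = .data$erev,
                     mg = mg_on & .data$receptor == "NMDA"),
    dplyr::transmute(config$drives, type = .data$cell, comp = .data$section,
                     tau1 = .data$tau1, tau2 = .data$tau2, erev = .data$erev,
                     mg = mg_on & .data$receptor == "NMDA"),
    tibble(type = c("olm", "bas"), comp = "soma",
           tau1 = config$ms$tau1, tau2 = config$ms$tau2, erev = config$ms$erev,
           mg = FALSE)
  ))
  req <- dplyr::arrange(req, .data$type, .data$comp, .data$tau1)
  slots <- split(req, req$type)
  nslot <- vapply(TYPE_ORDER, function(ty) {
    if (is.null(slots[[ty]])) 0L else nrow(slots[[ty]])
  }, integer(1))
  syn_base <- cumsum(c(0L, nslot[cell_type][-ncell]))  # 0-based per cell
  nsyn <- sum(nslot[cell_type])

  syn_comp <- integer(nsyn); syn_E <- numeric(nsyn)
  syn_t1 <- numeric(nsyn); syn_t2 <- numeric(nsyn)
  syn_mg <- integer(nsyn)
  for (ty in TYPE_ORDER) {
    st <- slots[[ty]]
    if (is.null(st) || !nrow(st)) next
    cells <- which(cell_type == ty)
    loc <- match(st$comp, geom[[ty]]$comp) - 1L
    for (s in seq_len(nrow(st))) {
      idx <- syn_base[cells] + s
      syn_comp[idx] <- comp_base[cells] + loc[s]
      syn_E[idx] <- st$erev[s]
      syn_t1[idx] <- st$tau1[s]
      syn_t2[idx] <- st$tau2[s]
      syn_mg[idx] <- as.integer(st$mg[s])
    }
  }

  slot_of <- function(ty, comp, tau1, tau2, erev) {
    st <- slots[[ty]]
    s <- which(st$comp == comp & abs(st$tau1 - tau1) < 1e-12 &
                 abs(st$tau2 - tau2) < 1e-12 & st$erev == erev)
    if (length(s) != 1L) abort("internal: synapse slot lookup failed")
    s
  }

  # network edges from the wiring
  wiring <- build_connectivity(pops, config$convergence, config$seed)
  ep <- integer(0); es <- integer(0); ew <- numeric(0); ed <- integer(0)
  for (i in seq_len(nrow(config$synapses))) {
    row <- config$synapses[i, ]
    w <- wiring[wiring$pre_pop == row$pre & wiring$post_pop == row$post, ]
    if (!nrow(w)) next
    delay <- row$delay +
      if (row$pre == "pyr" && row$post == "pyr") config$added_rec_delay else 0
    s <- slot_of(row$post, row$target, row$tau1, row$tau2, row$erev)
    post_global <- pop_offset[row$post] + w$post_id
    ep <- c(ep, pop_offset[row$pre] + w$pre_id)            # 1-based cell
    es <- c(es, syn_base[post_global] + s - 1L)            # 0-based synapse
    ew <- c(ew, rep(row$g, nrow(w)))
    ed <- c(ed, rep(as.integer(round(delay / config$dt)), nrow(w)))
  }
  ord <- order(ep)
  ep <- as.integer(ep[ord]); es <- es[ord]; ew <- ew[ord]; ed <- ed[ord]
  edge_ptr <- as.integer(c(0L, cumsum(tabulate(ep, nbins = ncell))))

  # background drive streams (one independent stream per cell x drive row)
  bg_syn <- integer(0); bg_rate <- numeric(0); bg_w <- numeric(0)
  bg_sid <- numeric(0)
  for (ty in TYPE_ORDER) {
    dty <- which(config$drives$cell == ty)
    cells <- which(cell_type == ty)
    for (k in seq_along(dty)) {
      row <- config$drives[dty[k], ]
      s <- slot_of(ty, row$section, row$tau1, row$tau2, row$erev)
      bg_syn <- c(bg_syn, syn_base[cells] + s - 1L)
      bg_rate <- c(bg_rate, rep(row$rate / 1000, length(cells)))
      bg_w <- c(bg_w, rep(row$g, length(cells)))
      bg_sid <- c(bg_sid, (cells - 1) * 16 + k)
    }
  }

  # medial septum pacemaker targets
  ms_cells <- which(cell_type %in% c("olm", "bas"))
  ms_syn <- vapply(ms_cells, function(c) {
    syn_base[c] + slot_of(cell_type[c], "soma", config$ms$tau1,
                          config$ms$tau2, config$ms$erev) - 1L
  }, integer(1))

  # initial conditions: rest with small seeded per-cell jitter
  jitter <- withr::with_seed(derive_seed(config$seed, "init"), {
    runif(ncell, -config$init_jitter, config$init_jitter)
  })
  vr <- if (length(config$v_rest) > 1) {
    unname(config$v_rest[cell_type])
  } else {
    rep(unname(config$v_rest), ncell)
  }
  v_init <- rep(vr, comp_n) + rep(jitter, comp_n)

  pyr_cells <- which(cell_type == "pyr")
  list(
    ncell = ncell, ncomp = ncomp, cell_type = cell_type,
    pop_offset = pop_offset, pops = pops,
    comp_base = comp_base, comp_n = comp_n,
    cap_nF = cap_nF, v_init = v_init,
    ax_i = as.integer(ax_i), ax_j = as.integer(ax_j), ax_g = ax_g,
    channels = channels,
    ca_comps = ca_comps, ca_area = ca_area,
    syn_comp = as.integer(syn_comp), syn_E = syn_E,
    syn_t1 = syn_t1, syn_t2 = syn_t2, syn_mg = syn_mg,
    syn_base = syn_base, slots = slots, slot_of = slot_of,
    soma_comp = comp_base,  # soma is local comp 1 (0-based offset 0)
    edge_ptr = edge_ptr, edge_pre = ep, edge_syn = as.integer(es),
    edge_w = ew, edge_delay = as.integer(ed),
    bg_syn = as.integer(bg_syn), bg_rate = bg_rate, bg_w = bg_w,
    bg_sid = bg_sid,
    ms_syn = as.integer(ms_syn),
    lfp_a3 = comp_base[pyr_cells] + 4L,  # Adend3, 0-based
    lfp_bd = comp_base[pyr_cells] + 1L,  # Bdend, 0-based
    wiring = wiring
  )
}

#' Run a seeded network simulation
#'
#' Integrates the full network for `duration` ms at the configured fixed step
#' and returns the spike raster together with the pyramidal dendritic voltage
#' recordings needed for the LFP. The first `discard` ms are kept in the
#' result but excluded from every analysis window (equilibration). Identical
#' config and seed give bit-identical results.
#'
#' @param config a `ca3_config`.
#' @param duration total simulated time (ms).
#' @param discard equilibration time excluded from analysis windows (ms).
#' @param record_all record per-cell Adend3/Bdend traces (memory-heavy; the
#'   population means needed for the LFP are always recorded).
#' @param drives,ms enable background Poisson drives / the theta pacemaker.
#' @param events optional tibble of scheduled synaptic events with columns
#'   `time`, `cell` (global id), `comp`, `tau1`, `tau2`, `erev`, `weight`.
#' @param fine_cells global cell ids whose somatic voltage is recorded at the
#'   integration step (for probe-style analyses).
#' @return an object of class `ca3_sim`.
#' @export
run_simulation <- function(config, duration = 7000, discard = 3000,
                           record_all = FALSE, drives = TRUE, ms = TRUE,
                           events = NULL, fine_cells = integer(0)) {
  stopifnot(inherits(config, "ca3_config"), duration > discard, discard >= 0)
  net <- build_network(config)

  ev_t <- numeric(0); ev_s <- integer(0); ev_w <- numeric(0)
  if (!is.null(events) && nrow(events)) {
    events <- events[order(events$time), ]
    ev_t <- events$time
    ev_s <- vapply(seq_len(nrow(events)), function(i) {
      c <- events$cell[i]
      net$syn_base[c] + net$slot_of(net$cell_type[c], events$comp[i],
                                    events$tau1[i], events$tau2[i],
                                    events$erev[i]) - 1L
    }, integer(1))
    ev_w <- events$weight
  }

  rec_comps <- integer(0)
  if (record_all) rec_comps <- c(net$lfp_a3, net$lfp_bd)
  fine_comps <- if (length(fine_cells)) net$soma_comp[fine_cells] else integer(0)

  inj_comp <- integer(0); inj_nA <- numeric(0)
  tonic <- config$tonic %||% c(pyr = 0, olm = 0, bas = 0)
  for (ty in TYPE_ORDER) {
    if (!is.null(tonic[ty]) && !is.na(tonic[ty]) && tonic[ty] != 0) {
      cells <- which(net$cell_type == ty)
      inj_comp <- c(inj_comp, net$soma_comp[cells])
      inj_nA <- c(inj_nA, rep(unname(tonic[ty]), length(cells)))
    }
  }

  raw <- cpp_run_network(
    net$cap_nF, net$v_init, net$ax_i, net$ax_j, net$ax_g,
    net$channels, min(VGRID), 0.1, length(VGRID),
    as.integer(net$ca_comps), config$ca$rest, config$ca$tau,
    config$ca$influx, net$ca_area,
    net$syn_comp, net$syn_E, net$syn_t1, net$syn_t2,
    net$syn_mg, config$nmda_mg$eta, config$nmda_mg$gamma,
    as.integer(net$soma_comp), config$spike_threshold,
    as.integer(round(config$refractory / config$dt)),
    net$edge_ptr, net$edge_syn, net$edge_w, net$edge_delay,
    if (drives) net$bg_syn else integer(0),
    if (drives) net$bg_rate else numeric(0),
    if (drives) net$bg_w else numeric(0),
    if (drives) net$bg_sid else numeric(0),
    if (ms) net$ms_syn else integer(0),
    if (ms) rep(config$ms$g, length(net$ms_syn)) else numeric(0),
    config$ms$period,
    ev_t, as.integer(ev_s), ev_w,
    as.integer(inj_comp), inj_nA,
    rep(0, length(inj_comp)), rep(duration, length(inj_comp)),
    config$dt, duration, as.numeric(config$seed),
    net$lfp_a3, net$lfp_bd,
    as.integer(round(config$record_dt / config$dt)),
    rec_comps, as.integer(fine_comps)
  )

  pop <- net$cell_type[raw$spike_cell]
  spikes <- tibble(
    time = raw$spike_t,
    cell = raw$spike_cell,
    population = pop,
    id = raw$spike_cell - net$pop_offset[pop]
  )
  structure(list(
    spikes = spikes,
    mean_adend3 = raw$mean_adend3,
    mean_bdend = raw$mean_bdend,
    voltages = if (record_all) raw$rec else NULL,
    fine = if (length(fine_cells)) raw$fine else NULL,
    record_dt = raw$rec_dt,
    dt = config$dt,
    duration = duration,
    discard = discard,
    populations = net$pops,
    config = config
  ), class = "ca3_sim")
}

#' @export
print.ca3_sim <- function(x, ...) {
  cat("<ca3_sim> ", x$duration, " ms (discard ", x$discard, " ms), ",
      nrow(x$spikes), " spikes; seed ", x$config$seed, "\n", sep = "")
  rates <- vapply(names(x$populations), function(p) {
    sum(x$spikes$population == p & x$spikes$time >= x$discard) /
      x$populations[[p]] / ((x$duration - x$discard) / 1000)
  }, numeric(1))
  cat("  mean rates (Hz):",
      paste(names(rates), round(rates, 2), sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Run a seed-matched control/scaled pair
#'
#' Both runs share the master seed, hence exactly the same wiring, background
#' event streams and initial conditions; only the scaled AMPA conductances
#' differ. This is the pairing used to define the relative gamma change.
#'
#' @inheritParams run_simulation
#' @param krec,kext scaling condition applied to the second run.
#' @return list with elements `control` and `scaled` (both `ca3_sim`).
#' @export
run_paired <- function(config, krec = 1, kext = 1, duration = 7000,
                       discard = 3000, ...) {
  list(
    control = run_simulation(config, duration, discard, ...),
    scaled = run_simulation(apply_scaling(config, krec = krec, kext = kext),
                            duration, discard, ...)
  )
}

#' Simulate a single isolated cell
#'
#' Runs one cell of the given type with all network input and background
#' drives silenced, optionally with a somatic (or dendritic) current step and
#' scheduled synaptic events. Voltages are returned at the integration step.
#'
#' @param type `"pyr"`, `"olm"` or `"bas"`.
#' @param config a `ca3_config` supplying geometry/channels.
#' @param duration simulated time (ms).
#' @param inj optional list `list(comp =, nA =, t0 =, t1 =)` current step.
#' @param events optional tibble (`time`, `comp`, `tau1`, `tau2`, `erev`,
#'   `weight`) of synaptic conductance events.
#' @param v0 initial voltage (mV; default the configured rest, no jitter).
#' @return tibble with `time` and one voltage column per compartment.
#' @export
simulate_cell <- function(type, config = NULL, duration = 500,
                          inj = NULL, events = NULL, v0 = NULL) {
  if (is.null(config)) config <- default_network_config()
  cfg <- config
  cfg$populations <- c(pyr = 0L, olm = 0L, bas = 0L)
  cfg$populations[type] <- 1L
  cfg$init_jitter <- 0
  if (!is.null(v0)) cfg$v_rest <- v0
  cfg$convergence$n <- 0L
  sim_events <- NULL
  if (!is.null(events)) {
    sim_events <- dplyr::mutate(events, cell = 1L)
  }
  inj_comp <- integer(0); inj_nA <- numeric(0)
  inj_t0 <- numeric(0); inj_t1 <- numeric(0)

  net <- build_network(cfg)
  if (!is.null(inj)) {
    loc <- match(inj$comp %||% "soma", cfg$geometry[[type]]$comp) - 1L
    inj_comp <- net$comp_base[1] + loc
    inj_nA <- inj$nA
    inj_t0 <- inj$t0 %||% 0
    inj_t1 <- inj$t1 %||% duration
  }
  ev_t <- numeric(0); ev_s <- integer(0); ev_w <- numeric(0)
  if (!is.null(sim_events) && nrow(sim_events)) {
    sim_events <- sim_events[order(sim_events$time), ]
    ev_t <- sim_events$time
    ev_s <- vapply(seq_len(nrow(sim_events)), function(i) {
      net$syn_base[1] + net$slot_of(type, sim_events$comp[i],
                                    sim_events$tau1[i], sim_events$tau2[i],
                                    sim_events$erev[i]) - 1L
    }, integer(1))
    ev_w <- sim_events$weight
  }
  all_comps <- net$comp_base[1] + seq_len(net$comp_n[1]) - 1L
  raw <- cpp_run_network(
    net$cap_nF, net$v_init, net$ax_i, net$ax_j, net$ax_g,
    net$channels, min(VGRID), 0.1, length(VGRID),
    as.integer(net$ca_comps), cfg$ca$rest, cfg$ca$tau,
    cfg$ca$influx, net$ca_area,
    net$syn_comp, net$syn_E, net$syn_t1, net$syn_t2,
    net$syn_mg, cfg$nmda_mg$eta, cfg$nmda_mg$gamma,
    as.integer(net$soma_comp), cfg$spike_threshold,
    as.integer(round(cfg$refractory / cfg$dt)),
    net$edge_ptr, net$edge_syn, net$edge_w, net$edge_delay,
    integer(0), numeric(0), numeric(0), numeric(0),
    integer(0), numeric(0), cfg$ms$period,
    ev_t, as.integer(ev_s), ev_w,
    as.integer(inj_comp), inj_nA, inj_t0, inj_t1,
    cfg$dt, duration, as.numeric(cfg$seed),
    integer(0), integer(0), 1L,
    integer(0), as.integer(all_comps)
  )
  out <- as_tibble(as.data.frame(raw$fine))
  names(out) <- cfg$geometry[[type]]$comp
  out <- dplyr::bind_cols(tibble(time = seq(0, duration, by = cfg$dt)), out)
  attr(out, "spike_times") <- raw$spike_t
  out
}

#' Detect spikes in a voltage trace
#'
#' Upward threshold crossings separated by at least the refractory interval.
#'
#' @param v voltage trace (mV), uniformly sampled.
#' @param dt sample interval (ms).
#' @param threshold detection threshold (mV).
#' @param refractory minimum inter-spike interval (ms).
#' @return strictly increasing spike times (ms).
#' @export
detect_spikes <- function(v, dt, threshold = 0, refractory = 3) {
  if (!length(v)) return(numeric(0))
  up <- which(v[-1] >= threshold & v[-length(v)] < threshold) + 1L
  times <- (up - 1) * dt
  keep <- numeric(0)
  last <- -Inf
  for (t in times) {
    if (t - last >= refractory) {
      keep <- c(keep, t)
      last <- t
    }
  }
  keep
}
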