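# Channel kinetics: canonical hippocampal Hodgkin-Huxley formulations.
# The model's channel *types* are fixed (transient Na, delayed-rectifier K,
# A-type K, Ih, high-threshold Ca, Ca-gated K, leak) but every rate parameter
# is carried in the config so kinetics can be re-aligned without touching code.

# x/(1 - exp(-x/y)) with the removable singularity at x = 0 filled in
vtrap <- function(x, y) {
  out <- x / (1 - exp(-x / y))
  small <- abs(x / y) < 1e-6
  out[small] <- y[1] * (1 + x[small] / y / 2)
  out
}

# Traub-style rate functions ------------------------------------------------

rates_na_m <- function(v) {
  a <- 0.32 * vtrap(v + 54, 4)
  b <- 0.28 * vtrap(-(v + 27), 5)
  list(inf = a / (a + b), tau = 1 / (a + b))
}

rates_na_h <- function(v) {
  a <- 0.128 * exp(-(v + 50) / 18)
  b <- 4 / (1 + exp(-(v + 27) / 5))
  list(inf = a / (a + b), tau = 1 / (a + b))
}

rates_kdr_n <- function(v) {
  a <- 0.032 * vtrap(v + 52, 5)
  b <- 0.5 * exp(-(v + 57) / 40)
  list(inf = a / (a + b), tau = 1 / (a + b))
}

rates_boltz <- function(v, vhalf, k, tau) {
  list(inf = 1 / (1 + exp(-(v - vhalf) / k)), tau = rep(tau, length(v)))
}

# Build lookup tables (steady state and 1 - exp(-dt/tau)) for one gate.
gate_table <- function(kind, v, dt, pars = list()) {
  shift <- pars$shift %||% 0
  ve <- v - shift
  r <- switch(kind,
    na_m = rates_na_m(ve),
    na_h = rates_na_h(ve),
    kdr_n = rates_kdr_n(ve),
    boltz = rates_boltz(ve, pars$vhalf, pars$k, pars$tau),
    abort(paste0("unknown gate kind: ", kind))
  )
  tau <- pmax(r$tau, 1e-3)
  list(minf = r$inf, edt = 1 - exp(-dt / tau), expn = as.integer(pars$expn %||% 1L))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Translate one channel spec (see default_channels()) into the gate tables the
# integrator consumes. `comps0` are 0-based global compartment indices and
# `gbar_nS` the matching absolute conductances.
channel_tables <- function(spec, comps0, gbar_nS, v, dt) {
  gates <- list()
  if (spec$kind == "na") {
    gates <- list(
      gate_table("na_m", v, dt, list(shift = spec$shift %||% 0, expn = 3L)),
      gate_table("na_h", v, dt, list(shift = spec$shift %||% 0, expn = 1L))
    )
  } else if (spec$kind == "kdr") {
    gates <- list(gate_table("kdr_n", v, dt, list(shift = spec$shift %||% 0, expn = 4L)))
  } else if (spec$kind == "boltz") {
    gates <- lapply(spec$gates, function(g) {
      gate_table("boltz", v, dt,
                 list(vhalf = g$vhalf, k = g$k, tau = g$tau, expn = g$expn %||% 1L))
    })
  } else if (spec$kind %in% c("leak", "cagate")) {
    gates <- list()
  } else {
    abort(paste0("unknown channel kind: ", spec$kind))
  }
  list(
    comps = as.integer(comps0), gbar = gbar_nS, erev = spec$erev,
    gates = gates,
    ca_source = isTRUE(spec$ca_source),
    ca_gated = identical(spec$kind, "cagate"),
    kd = spec$kd %||% 0
  )
}

# Default conductance-density sets (S/cm2) per cell type. Densities follow
# common hippocampal multicompartment practice: fast Na/Kdr strongest at the
# soma, A-type K and a weak Ih throughout the pyramidal tree, and an
# Ih + L-type Ca + K(Ca) complement that gives OLM cells burst firing with a
# Ca-dependent after-burst pause.
default_channels <- function() {
  list(
    pyr = list(
      na = list(kind = "na", erev = 55, shift = 0,
                g = c(soma = 0.08, Bdend = 0.04, Adend1 = 0.04,
                      Adend2 = 0.04, Adend3 = 0.04)),
      kdr = list(kind = "kdr", erev = -90, shift = 0,
                 g = c(soma = 0.06, Bdend = 0.04, Adend1 = 0.04,
                       Adend2 = 0.04, Adend3 = 0.04)),
      ka = list(kind = "boltz", erev = -90,
                g = c(soma = 0.002, Bdend = 0.002, Adend1 = 0.002,
                      Adend2 = 0.002, Adend3 = 0.002),
                gates = list(
                  list(vhalf = -10, k = 15, tau = 2, expn = 1L),
                  list(vhalf = -60, k = -6, tau = 20, expn = 1L)
                )),
      ih = list(kind = "boltz", erev = -30,
                g = c(soma = 1e-4, Bdend = 1e-4, Adend1 = 1e-4,
                      Adend2 = 1e-4, Adend3 = 1e-4),
                gates = list(list(vhalf = -81, k = -8, tau = 80, expn = 1L))),
      leak = list(kind = "leak", erev = -65,
                  g = c(soma = 1.2e-4, Bdend = 1.2e-4, Adend1 = 1.2e-4,
                        Adend2 = 1.2e-4, Adend3 = 1.2e-4))
    ),
    olm = list(
      na = list(kind = "na", erev = 55, shift = 0, g = c(soma = 0.08)),
      kdr = list(kind = "kdr", erev = -90, shift = 0, g = c(soma = 0.06)),
      ih = list(kind = "boltz", erev = -30, g = c(soma = 2e-4),
                gates = list(list(vhalf = -84, k = -10.2, tau = 60, expn = 1L))),
      cal = list(kind = "boltz", erev = 120, g = c(soma = 1.25e-3),
                 ca_source = TRUE,
                 gates = list(list(vhalf = -20, k = 9, tau = 1.5, expn = 2L))),
      kca = list(kind = "cagate", erev = -90, g = c(soma = 2e-3), kd = 3e-3),
      leak = list(kind = "leak", erev = -67, g = c(soma = 1e-4))
    ),
    bas = list(
      na = list(kind = "na", erev = 55, shift = 0, g = c(soma = 0.10)),
      kdr = list(kind = "kdr", erev = -90, shift = 0, g = c(soma = 0.08)),
      leak = list(kind = "leak", erev = -67, g = c(soma = 1.5e-4))
    )
  )
}
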