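#' Peak-normalized double-exponential synaptic kernel
#'
#' Conductance time course \eqn{N (e^{-t/\tau_2} - e^{-t/\tau_1})} for
#' \eqn{t \ge 0} (0 for \eqn{t < 0}), with the normalization constant `N`
#' chosen so the peak equals 1 — the tabulated `g` values are then peak
#' conductances and multiplicative scaling factors act exactly on the peak.
#'
#' @param t time since onset (ms); vectorized.
#' @param tau1 rise time constant (ms).
#' @param tau2 fall time constant (ms); must exceed `tau1`.
#' @return dimensionless conductance factor in \[0, 1\].
#' @export
double_exp_kernel <- function(t, tau1, tau2) {
  if (!(tau2 > tau1 && tau1 > 0)) {
    abort("double_exp_kernel requires 0 < tau1 < tau2")
  }
  out <- numeric(length(t))
  pos <- t >= 0
  N <- 1 / (exp(-syn_peak_time(tau1, tau2) / tau2) -
              exp(-syn_peak_time(tau1, tau2) / tau1))
  out[pos] <- N * (exp(-t[pos] / tau2) - exp(-t[pos] / tau1))
  out
}

#' Time of peak of the double-exponential kernel
#'
#' Closed form \eqn{t^* = \tau_1 \tau_2 / (\tau_2 - \tau_1) \ln(\tau_2/\tau_1)}.
#'
#' @inheritParams double_exp_kernel
#' @export
syn_peak_time <- function(tau1, tau2) {
  tau1 * tau2 / (tau2 - tau1) * log(tau2 / tau1)
}

#' Homogeneous Poisson event times
#'
#' @param rate event rate (Hz).
#' @param duration window length (ms).
#' @param seed integer seed (the draw is isolated from the global RNG state).
#' @return sorted event times in \[0, duration) ms.
#' @export
poisson_events <- function(rate, duration, seed = 1L) {
  stopifnot(rate >= 0, duration > 0)
  if (rate == 0) return(numeric(0))
  withr::with_seed(as.integer(seed), {
    n <- rpois(1, rate * duration / 1000)
    sort(runif(n, 0, duration))
  })
}

#' Medial-septum theta pacemaker schedule
#'
#' The MS drive periodically (every 150 ms by default) inhibits all basket
#' and OLM cells with a slow double-exponential GABAergic conductance
#' (rise 20 ms, fall 40 ms, reversal -80 mV, peak 1.6 nS). Events fire at
#' t = 0, period, 2*period, ... ms.
#'
#' @param duration simulation length (ms).
#' @param period pacing period (ms).
#' @return tibble with `time` (ms) plus the kernel parameters as attributes.
#' @export
ms_theta_drive <- function(duration, period = 150) {
  stopifnot(duration > 0)
  times <- seq(0, duration, by = period)
  times <- times[times <= duration]
  structure(tibble(time = times),
            tau1 = 20, tau2 = 40, erev = -80, g = 1.6)
}
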