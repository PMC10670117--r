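# Synthetic fixtures: desk-scale inputs with the statistical structure the
# analyses assume, so the signal and inference chains are testable without
# running the simulator.

#' Surrogate LFP: sinusoids plus Gaussian noise
#'
#' Sum of known oscillatory components with white noise; band powers are
#' computable in closed form (a sine of amplitude A contributes A^2/2 of
#' variance to its own frequency).
#'
#' @param duration length (s).
#' @param fs sample rate (Hz); must exceed twice the fastest component.
#' @param components tibble/data.frame with `frequency` (Hz), `amplitude`,
#'   and optional `phase` (rad).
#' @param noise_sd Gaussian noise SD.
#' @param seed integer seed.
#' @return an `lfp_trace` (tibble `time` ms, `value`).
#' @export
make_surrogate_lfp <- function(duration = 4, fs = 1000,
                               components = data.frame(frequency = 40,
                                                       amplitude = 1),
                               noise_sd = 0, seed = 1L) {
  if (nrow(components) && fs <= 2 * max(components$frequency)) {
    abort("sample rate must exceed twice the fastest component (aliasing)")
  }
  n <- round(duration * fs)
  t <- seq_len(n) / fs
  v <- numeric(n)
  for (i in seq_len(nrow(components))) {
    ph <- if ("phase" %in% names(components)) components$phase[i] else 0
    v <- v + components$amplitude[i] *
      sin(2 * pi * components$frequency[i] * t + ph)
  }
  if (noise_sd > 0) {
    v <- v + withr::with_seed(as.integer(seed), rnorm(n, 0, noise_sd))
  }
  structure(tibble(time = t * 1000, value = v),
            fs = fs, window = c(0, duration * 1000),
            class = c("lfp_trace", class(tibble())))
}

#' Surrogate spike raster with known rhythmicity
#'
#' Population volleys at `rhythm_freq` with per-spike Gaussian jitter; the
#' pooled rate matches `n_cells * rate` in expectation. With zero jitter the
#' pooled-raster spectrum peaks exactly at the rhythm frequency; as jitter
#' grows the raster approaches a homogeneous Poisson train.
#'
#' @param n_cells number of cells.
#' @param rhythm_freq volley frequency (Hz).
#' @param rate per-cell mean rate (Hz).
#' @param jitter per-spike Gaussian jitter SD (ms).
#' @param duration length (ms).
#' @param seed integer seed.
#' @return tibble `time` (ms), `cell`, `population` (= "syn").
#' @export
make_surrogate_raster <- function(n_cells = 100, rhythm_freq = 40, rate = 4,
                                  jitter = 1, duration = 4000, seed = 1L) {
  stopifnot(rate >= 0, n_cells >= 1)
  if (rate == 0) {
    return(tibble(time = numeric(0), cell = integer(0),
                  population = character(0)))
  }
  period <- 1000 / rhythm_freq
  volleys <- seq(period / 2, duration, by = period)
  p_spike <- rate * 1000 / rhythm_freq / 1000  # per cell per volley
  withr::with_seed(as.integer(seed), {
    rows <- lapply(seq_len(n_cells), function(c) {
      hit <- volleys[runif(length(volleys)) < p_spike]
      if (!length(hit)) return(NULL)
      tibble(time = hit + rnorm(length(hit), 0, jitter), cell = c)
    })
    out <- dplyr::bind_rows(rows)
  })
  out <- out[out$time >= 0 & out$time < duration, ]
  out <- out[order(out$time), ]
  out$population <- "syn"
  out
}

#' Synthetic mediation dataset with planted path coefficients
#'
#' `X` uniform over the scaling levels \{1, 1.25, 1.5, 1.75\};
#' `M = a X + e`, `Y = c_direct X + b M + e'` with independent Gaussian
#' noise, so ACME = a*b and ADE = c_direct on the unstandardized scale.
#'
#' @param a,b,c_direct planted path coefficients.
#' @param n rows (>= 10).
#' @param noise_m,noise_y noise SDs for mediator and outcome.
#' @param seed integer seed.
#' @return tibble with columns `X`, `M`, `Y`.
#' @export
make_mediation_dataset <- function(a = 0.8, b = 0.9, c_direct = 0, n = 256,
                                   noise_m = 0.1, noise_y = 0.1, seed = 1L) {
  stopifnot(n >= 10)
  withr::with_seed(as.integer(seed), {
    X <- sample(c(1, 1.25, 1.5, 1.75), n, replace = TRUE)
    M <- a * X + rnorm(n, 0, noise_m)
    Y <- c_direct * X + b * M + rnorm(n, 0, noise_y)
  })
  tibble(X = X, M = M, Y = Y)
}
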