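# LFP construction, Welch spectra, band power, delta-gamma, raster gamma,
# firing rates, and the surrogate fixtures that exercise them.

test_that("compute_lfp is the pyramidal mean of distal-minus-basal voltage", {
  m <- matrix(rnorm(400), 100, 4)
  same <- compute_lfp(list(adend3 = m, bdend = m, fs = 1000))
  expect_true(all(same$value == 0))
  one <- compute_lfp(list(adend3 = m[, 1, drop = FALSE],
                          bdend = 0 * m[, 1, drop = FALSE], fs = 1000))
  expect_equal(one$value, m[, 1])
  # common-mode rejection: adding any common signal changes nothing
  cm <- matrix(rnorm(100), 100, 4)
  a <- compute_lfp(list(adend3 = m, bdend = 0.5 * m, fs = 1000))
  b <- compute_lfp(list(adend3 = m + cm, bdend = 0.5 * m + cm, fs = 1000))
  expect_equal(a$value, b$value)
  # linearity
  m2 <- matrix(rnorm(400), 100, 4)
  ab <- compute_lfp(list(adend3 = m + m2, bdend = 0 * m, fs = 1000))
  expect_equal(ab$value,
               compute_lfp(list(adend3 = m, bdend = 0 * m, fs = 1000))$value +
                 compute_lfp(list(adend3 = m2, bdend = 0 * m2, fs = 1000))$value)
})

test_that("Welch spectrum recovers sine amplitude and satisfies Parseval", {
  x <- make_surrogate_lfp(duration = 4, fs = 1000,
                          components = data.frame(frequency = 40, amplitude = 2))
  ps <- welch_power(x)
  expect_equal(peak_frequency(ps), 40)
  df <- ps$frequency[2] - ps$frequency[1]
  # integrated density ~ variance = A^2/2
  expect_equal(sum(ps$power) * df, 2^2 / 2, tolerance = 0.05)
  # band power concentrates at the component
  expect_gt(band_power(ps, 30, 100) / sum(ps$power), 0.98)
  expect_lt(band_power(ps, 101, 200) / band_power(ps, 30, 100), 1e-4)
})

test_that("white noise gives a flat spectrum and constants only DC", {
  x <- make_surrogate_lfp(duration = 8, fs = 500,
                          components = data.frame(frequency = numeric(0),
                                                  amplitude = numeric(0)),
                          noise_sd = 1, seed = 4)
  ps <- welch_power(x)
  sel <- ps$frequency > 5 & ps$frequency < 240
  fit <- lm(log(power) ~ frequency, data = ps[sel, ])
  expect_lt(abs(coef(fit)[2]), 2e-3)
  ps0 <- welch_power(rep(3, 2000), fs = 1000)
  expect_equal(sum(ps0$power[-1]), 0, tolerance = 1e-20)
  expect_error(welch_power(rnorm(100), fs = 1000, segment_len = 1), "short")
})

test_that("band_power partitions total power and rejects empty bands", {
  x <- make_surrogate_lfp(duration = 4, fs = 1000,
                          components = data.frame(frequency = c(10, 60),
                                                  amplitude = c(1, 1)),
                          noise_sd = 0.2, seed = 9)
  ps <- welch_power(x)
  total <- sum(ps$power)
  expect_equal(band_power(ps, 0, 500), total)
  # partition property
  expect_equal(band_power(ps, 0, 29.5) + band_power(ps, 29.6, 500), total,
               tolerance = 1e-12)
  # two equal sines: gamma band holds about half the oscillatory power
  expect_equal(band_power(ps, 30, 100) / total, 0.5, tolerance = 0.1)
  expect_error(band_power(ps, 501, 600), "band")
})

test_that("delta_gamma is the ratio-minus-one with a positive-control guard", {
  expect_equal(delta_gamma(2, 2), 0)
  expect_equal(delta_gamma(4, 2), 1)
  expect_equal(delta_gamma(1, 2), -0.5)
  expect_error(delta_gamma(1, 0), "positive")
})

test_that("raster gamma finds rhythmic pooled spiking and ignores labels", {
  expect_equal(raster_gamma(tibble::tibble(time = numeric(0)), c(0, 4000)), 0)
  r <- make_surrogate_raster(n_cells = 200, rhythm_freq = 40, rate = 4,
                             jitter = 0, duration = 4000, seed = 3)
  sig <- ca3gamma:::raster_signal(r, c(0, 4000))
  ps <- welch_power(sig$value, fs = 1000)
  expect_equal(peak_frequency(ps, 10, 200), 40)
  # relabeling cells leaves the pooled statistic unchanged
  r2 <- r
  r2$cell <- rev(r2$cell)
  expect_equal(raster_gamma(r2, c(0, 4000)), raster_gamma(r, c(0, 4000)))
  # heavy jitter destroys the spectral peak
  rj <- make_surrogate_raster(n_cells = 200, rhythm_freq = 40, rate = 4,
                              jitter = 40, duration = 4000, seed = 3)
  sj <- ca3gamma:::raster_signal(rj, c(0, 4000))
  pj <- welch_power(sj$value, fs = 1000)
  peak_ratio <- function(p) p$power[p$frequency == 40] /
    mean(p$power[p$frequency >= 20 & p$frequency <= 60 & p$frequency != 40])
  expect_gt(peak_ratio(ps), 20)
  expect_lt(peak_ratio(pj), 3)
})

test_that("mean_rate counts spikes per cell per second", {
  sp <- tibble::tibble(time = seq_len(800), population = "pyr")
  expect_equal(mean_rate(sp, "pyr", window = c(0, 4000), n_cells = 800), 0.25)
  expect_equal(mean_rate(tibble::tibble(time = numeric(0),
                                        population = character(0)),
                         "pyr", window = c(0, 1000), n_cells = 10), 0)
  sp3 <- tibble::tibble(time = seq(1 / 6, 1000, by = 1 / 3),
                        population = "olm")
  expect_equal(mean_rate(sp3, "olm", window = c(0, 1000), n_cells = 1000), 3,
               tolerance = 1e-6)
})

test_that("surrogate LFP obeys closed-form band powers and quadratic scaling", {
  a1 <- band_power(welch_power(make_surrogate_lfp(
    components = data.frame(frequency = 40, amplitude = 1))), 30, 100)
  a2 <- band_power(welch_power(make_surrogate_lfp(
    components = data.frame(frequency = 40, amplitude = 2))), 30, 100)
  df <- 1  # 1 s segments at 1 kHz
  expect_equal(a1 * df, 0.5, tolerance = 0.05)
  expect_equal(a2 / a1, 4, tolerance = 0.02)
  z <- make_surrogate_lfp(components = data.frame(frequency = numeric(0),
                                                  amplitude = numeric(0)))
  expect_true(all(z$value == 0))
  expect_error(make_surrogate_lfp(fs = 60,
                                  components = data.frame(frequency = 40,
                                                          amplitude = 1)),
               "alias")
})

test_that("surrogate raster pooled rate matches expectation", {
  r <- make_surrogate_raster(n_cells = 100, rhythm_freq = 40, rate = 4,
                             jitter = 1, duration = 8000, seed = 5)
  expect_equal(nrow(r) / 100 / 8, 4, tolerance = 0.1)
  expect_equal(nrow(make_surrogate_raster(rate = 0)), 0)
})
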