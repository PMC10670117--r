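# Cell-level biophysics: resting stability, excitability, burst dynamics,
# spike detection, and integration-step convergence.

test_that("isolated cells settle to a stable subthreshold rest", {
  for (type in c("pyr", "olm", "bas")) {
    tr <- simulate_cell(type, duration = 800)
    tail_v <- tr$soma[tr$time >= 300]
    expect_lt(diff(range(tail_v)), 2)        # within +-1 mV band once settled
    expect_lt(max(tail_v), -50)              # subthreshold
    expect_length(attr(tr, "spike_times"), 0)
  }
})

test_that("suprathreshold current step elicits action potentials with positive overshoot", {
  tr <- simulate_cell("pyr", duration = 600,
                      inj = list(comp = "soma", nA = 0.2, t0 = 100, t1 = 500))
  sp <- attr(tr, "spike_times")
  expect_gte(length(sp), 1)
  expect_gt(max(tr$soma), 0)
  expect_true(all(sp >= 100 & sp <= 505))
})

test_that("pyramidal rheobase agrees between the default and a refined integration step", {
  rheo <- function(dt) {
    cfg <- default_network_config()
    cfg$dt <- dt
    lo <- 0; hi <- 0.4
    for (i in 1:8) {
      mid <- (lo + hi) / 2
      tr <- simulate_cell("pyr", cfg, duration = 400,
                          inj = list(comp = "soma", nA = mid, t0 = 100, t1 = 400))
      if (length(attr(tr, "spike_times"))) hi <- mid else lo <- mid
    }
    (lo + hi) / 2
  }
  r1 <- rheo(0.025)
  r2 <- rheo(0.0125)  # fine-step reference
  expect_gt(r1, 0.01)
  expect_lt(abs(r1 - r2) / r2, 0.1)
})

test_that("OLM cells burst and then pause through the Ca-activated K current", {
  tr <- simulate_cell("olm", duration = 1200,
                      inj = list(comp = "soma", nA = 0.1, t0 = 100, t1 = 1100))
  sp <- attr(tr, "spike_times")
  expect_gte(length(sp), 3)
  isi <- diff(sp)
  # at least one interval much longer than the burst intervals
  expect_gt(max(isi) / min(isi), 3)
  # removing the Ca-gated K current abolishes the long pauses
  cfg <- default_network_config()
  cfg$channels$olm$kca$g <- c(soma = 0)
  tr2 <- simulate_cell("olm", cfg, duration = 1200,
                       inj = list(comp = "soma", nA = 0.1, t0 = 100, t1 = 1100))
  expect_gt(length(attr(tr2, "spike_times")), length(sp))
})

test_that("halving dt changes spike timing by less than half a millisecond per spike", {
  times_at <- function(dt) {
    cfg <- default_network_config()
    cfg$dt <- dt
    tr <- simulate_cell("pyr", cfg, duration = 1000,
                        inj = list(comp = "soma", nA = 0.3, t0 = 100, t1 = 900))
    attr(tr, "spike_times")
  }
  t1 <- times_at(0.025)
  t2 <- times_at(0.0125)
  t3 <- times_at(0.00625)
  n <- min(length(t1), length(t2))
  expect_gt(n, 20)
  expect_equal(length(t1), length(t2), tolerance = 0.1)
  # accumulated phase drift, per spike
  drift <- abs(t1[1:n] - t2[1:n]) / seq_len(n)
  expect_lt(max(drift[-(1:3)]), 0.5)
  # and the period error shrinks roughly linearly with dt (first-order scheme)
  err <- function(a, b) {
    m <- min(length(a), length(b))
    abs(mean(diff(a[1:m])) - mean(diff(b[1:m])))
  }
  expect_lt(err(t2, t3), err(t1, t2))
})

test_that("voltages stay finite under strong noisy input (gating bounds hold)", {
  ev <- tibble::tibble(
    time = sort(runif(500, 0, 1000)),
    comp = "soma", tau1 = 0.05, tau2 = 5.3, erev = 0,
    weight = runif(500, 0, 10)
  )
  tr <- simulate_cell("pyr", duration = 1000, events = ev)
  expect_true(all(is.finite(as.matrix(tr[-1]))))
  expect_lt(max(tr$soma), 80)
  expect_gt(min(tr$soma), -120)
})

test_that("detect_spikes finds threshold crossings with refractoriness", {
  expect_identical(detect_spikes(numeric(0), 0.1), numeric(0))
  expect_identical(detect_spikes(rep(-65, 1000), 0.1), numeric(0))
  v <- rep(-65, 1000); v[500] <- 10
  expect_equal(detect_spikes(v, 0.1), (500 - 1) * 0.1)
  # synthetic 40 Hz spike train sampled at 10 kHz: crossings every 25 ms
  dt <- 0.1
  t <- seq(0, 999.9, by = dt)
  v <- -65 + 80 * ((t %% 25) >= 5 & (t %% 25) < 5.3)
  got <- detect_spikes(v, dt, threshold = 0, refractory = 3)
  want <- seq(5, 980, by = 25)
  expect_equal(length(got), length(want))
  expect_lt(max(abs(got - want)), dt + 1e-9)
  expect_true(all(diff(got) >= 3))
})
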