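# Simulation-engine contracts on the desk-scale (80/20/20) network.

test_that("identical seed gives bit-identical rasters; seeds differ", {
  cfg <- tiny_cfg(seed = 4)
  s1 <- run_simulation(cfg, 1500, 500)
  s2 <- run_simulation(cfg, 1500, 500)
  expect_identical(s1$spikes, s2$spikes)
  expect_identical(s1$mean_adend3, s2$mean_adend3)
  s3 <- run_simulation(tiny_cfg(seed = 5), 1500, 500)
  expect_false(identical(s1$spikes, s3$spikes))
})

test_that("with all drives, pacing and tonic currents off the network is silent", {
  cfg <- tiny_cfg(seed = 4)
  cfg$tonic[] <- 0
  sim <- run_simulation(cfg, 1000, 0, drives = FALSE, ms = FALSE)
  expect_equal(nrow(sim$spikes), 0)
})

test_that("recording options do not perturb the dynamics", {
  cfg <- tiny_cfg(seed = 6)
  plain <- run_simulation(cfg, 1200, 200)
  probed <- run_simulation(cfg, 1200, 200, record_all = TRUE,
                           fine_cells = c(1L, 81L))
  expect_identical(plain$spikes, probed$spikes)
  # per-cell traces average to the stored population means
  lfp_full <- compute_lfp(probed)
  lfp_mean <- compute_lfp(plain)
  expect_equal(lfp_full$value, lfp_mean$value, tolerance = 1e-10)
})

test_that("paired runs share wiring and background streams exactly", {
  cfg <- tiny_cfg(seed = 8)
  pair0 <- run_paired(cfg, krec = 1, kext = 1, duration = 1200, discard = 200)
  expect_identical(pair0$control$spikes, pair0$scaled$spikes)
  pair <- run_paired(cfg, krec = 1, kext = 1.75, duration = 1200, discard = 200)
  n1 <- ca3gamma:::build_network(pair$control$config)
  n2 <- ca3gamma:::build_network(pair$scaled$config)
  expect_identical(n1$edge_syn, n2$edge_syn)   # same wiring
  expect_identical(n1$edge_pre, n2$edge_pre)
  expect_identical(n1$bg_sid, n2$bg_sid)       # same event streams
  expect_false(identical(pair$control$mean_adend3, pair$scaled$mean_adend3))
})

test_that("spike raster is consistent with population sizes and the window", {
  cfg <- tiny_cfg(seed = 4)
  sim <- run_simulation(cfg, 1500, 500)
  expect_true(all(sim$spikes$time >= 0 & sim$spikes$time <= 1500))
  expect_true(all(sim$spikes$population %in% c("pyr", "olm", "bas")))
  with(sim$spikes, {
    expect_true(all(id[population == "pyr"] <= 80))
    expect_true(all(id[population == "olm"] <= 20))
    expect_true(all(id[population == "bas"] <= 20))
  })
  # spike times strictly increasing per cell with refractory separation
  by_cell <- split(sim$spikes$time, sim$spikes$cell)
  gaps <- unlist(lapply(by_cell, diff))
  expect_true(all(gaps > cfg$refractory - 1e-9))
})

test_that("the theta pacemaker imposes 150 ms periodicity on the network", {
  cfg <- tiny_cfg(seed = 2)
  on <- run_simulation(cfg, 4000, 1000)
  off <- run_simulation(cfg, 4000, 1000, ms = FALSE)
  win <- c(1000, 4000)
  s_on <- theta_strength(on$spikes, win)
  s_off <- theta_strength(off$spikes, win)
  expect_gt(s_on, s_off + 0.05)
  expect_gt(s_on, 0.1)
})

test_that("the desk-scale network completes a full-protocol run quickly", {
  cfg <- tiny_cfg(seed = 3)
  t0 <- Sys.time()
  sim <- run_simulation(cfg, 7000, 3000)
  expect_lt(as.numeric(Sys.time() - t0, units = "secs"), 120)
  expect_gt(nrow(sim$spikes), 0)
  expect_equal(length(sim$mean_adend3), 7001)
})
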