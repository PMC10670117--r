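# Regression and mediation inference on synthetic tables with planted truth.

test_that("standardize gives exact z-scores, idempotence and affine invariance", {
  d <- tibble::tibble(x = rep(c(1, 1.25, 1.5, 1.75), 16))
  s <- standardize(d)
  expect_equal(mean(s$x), 0)
  expect_equal(sd(s$x), 1)
  expect_equal(standardize(s)$x, s$x)
  expect_equal(standardize(tibble::tibble(x = 3 * d$x - 7))$x, s$x)
  expect_error(standardize(tibble::tibble(x = rep(1, 10))), "constant")
})

test_that("delta-gamma regression is exact on noiseless data and order-invariant", {
  g <- expand.grid(krec = c(1, 1.25, 1.5, 1.75), kext = c(1, 1.25, 1.5, 1.75))
  g$delta_gamma <- -1.3 + 1.17 * g$kext + 0.13 * g$krec
  fit <- fit_delta_gamma_regression(g)
  # a noiseless fit makes summary.lm warn about the perfect fit; that is the
  # point of the check
  td <- suppressWarnings(tidy(fit))
  expect_equal(td$estimate[td$term == "kext"], 1.17, tolerance = 1e-10)
  expect_equal(td$estimate[td$term == "krec"], 0.13, tolerance = 1e-10)
  expect_equal(suppressWarnings(glance(fit))$r.squared, 1)
  fit2 <- fit_delta_gamma_regression(g[sample(nrow(g)), ])
  expect_equal(suppressWarnings(tidy(fit2))$estimate, td$estimate)
  g$krec <- 1
  expect_error(fit_delta_gamma_regression(g), "deficient")
})

test_that("regression recovers planted coefficients with calibrated CIs", {
  nrep <- 200
  hits1 <- 0; hits2 <- 0; errs <- numeric(nrep)
  for (r in seq_len(nrep)) {
    d <- withr::with_seed(r, {
      x1 <- sample(c(1, 1.25, 1.5, 1.75), 256, TRUE)
      x2 <- sample(c(1, 1.25, 1.5, 1.75), 256, TRUE)
      tibble::tibble(kext = x1, krec = x2,
                     delta_gamma = 1.2 * x1 + 0 * x2 + rnorm(256, 0, 0.1))
    })
    td <- tidy(fit_delta_gamma_regression(d))
    b1 <- td[td$term == "kext", ]
    b2 <- td[td$term == "krec", ]
    hits1 <- hits1 + (b1$conf.low <= 1.2 && 1.2 <= b1$conf.high)
    hits2 <- hits2 + (b2$conf.low <= 0 && 0 <= b2$conf.high)
    errs[r] <- b1$estimate - 1.2
  }
  expect_gte(hits1 / nrep, 0.9)
  expect_gte(hits2 / nrep, 0.9)
  # unbiasedness: mean error a small fraction of the sampling SD
  expect_lt(abs(mean(errs)), 0.15 * sd(errs))
})

test_that("mediation point estimates satisfy TE = ACME + ADE exactly", {
  d <- make_mediation_dataset(a = 0.8, b = 0.9, c_direct = 0.3, n = 200,
                              seed = 11)
  m <- mediation_analysis(d, "X", "M", "Y", n_boot = 200, seed = 1)
  est <- tidy(m)$estimate
  names(est) <- tidy(m)$term
  expect_equal(est[["total_effect"]], est[["acme"]] + est[["ade"]],
               tolerance = 1e-10)
  expect_equal(est[["prop_mediated"]], est[["acme"]] / est[["total_effect"]],
               tolerance = 1e-10)
})

test_that("full mediation is detected when there is no direct path", {
  d <- make_mediation_dataset(a = 0.8, b = 0.9, c_direct = 0, n = 256,
                              noise_m = 0.1, noise_y = 0.1, seed = 5)
  m <- tidy(mediation_analysis(d, "X", "M", "Y", n_boot = 500, seed = 2))
  ade <- m[m$term == "ade", ]
  acme <- m[m$term == "acme", ]
  prop <- m[m$term == "prop_mediated", ]
  expect_true(ade$conf.low <= 0 && 0 <= ade$conf.high)
  expect_gt(acme$conf.low, 0)
  expect_equal(prop$estimate, 1, tolerance = 0.1)
})

test_that("ACME vanishes when the outcome ignores the mediator", {
  d <- make_mediation_dataset(a = 0.8, b = 0, c_direct = 0.7, n = 256,
                              seed = 8)
  m <- tidy(mediation_analysis(d, "X", "M", "Y", n_boot = 300, seed = 3))
  expect_equal(m$estimate[m$term == "acme"], 0, tolerance = 0.05)
  expect_gt(m$estimate[m$term == "ade"], 0.5)
})

test_that("planted mediation paths are recovered within bootstrap intervals", {
  # standardized-scale truth for X~{levels}, M = aX+e, Y = bM + c'X + e'
  cover <- 0
  for (r in 1:25) {
    d <- make_mediation_dataset(a = 0.6, b = 0.5, c_direct = 0.2, n = 256,
                                noise_m = 0.15, noise_y = 0.15, seed = 100 + r)
    sx <- sd(d$X); sy <- sd(d$Y)
    truth_te <- (0.6 * 0.5 + 0.2) * sx / sy
    m <- tidy(mediation_analysis(d, "X", "M", "Y", n_boot = 200,
                                 seed = r))
    te <- m[m$term == "total_effect", ]
    cover <- cover + (te$conf.low <= truth_te && truth_te <= te$conf.high)
  }
  expect_gte(cover / 25, 0.8)
})

test_that("degenerate mediation inputs are rejected", {
  d <- make_mediation_dataset(n = 50, seed = 1)
  d$M <- 1
  expect_error(mediation_analysis(d, "X", "M", "Y"), "variance")
  expect_error(mediation_analysis(make_mediation_dataset(n = 12, seed = 1)[1:5, ],
                                  "X", "M", "Y"), "rows")
})

test_that("mediation dataset generator honors planted parameters", {
  d0 <- make_mediation_dataset(a = 0.8, b = 0.9, c_direct = 0.1, n = 64,
                               noise_m = 0, noise_y = 0, seed = 2)
  expect_equal(d0$M, 0.8 * d0$X)
  expect_equal(d0$Y, 0.1 * d0$X + 0.9 * d0$M)
  expect_true(all(d0$X %in% c(1, 1.25, 1.5, 1.75)))
  expect_identical(make_mediation_dataset(seed = 7),
                   make_mediation_dataset(seed = 7))
})
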