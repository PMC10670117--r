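#' Z-score columns of a table
#'
#' @param data data frame / tibble.
#' @param cols columns to standardize (character; default all numeric).
#' @return tibble with the selected columns centred to mean 0, SD 1.
#' @export
standardize <- function(data, cols = NULL) {
  data <- as_tibble(data)
  if (is.null(cols)) {
    cols <- names(data)[vapply(data, is.numeric, logical(1))]
  }
  for (cl in cols) {
    s <- sd(data[[cl]])
    if (!is.finite(s) || s == 0) {
      abort(paste0("cannot standardize constant column: ", cl))
    }
    data[[cl]] <- (data[[cl]] - mean(data[[cl]])) / s
  }
  data
}

#' Regression of delta-gamma on the scaling factors
#'
#' Ordinary least squares `delta_gamma ~ kext + krec` on the grid table,
#' with classical standard errors, two-sided t-test p-values and 95%
#' confidence intervals, matching the reporting layout of the scaling-grid
#' analysis. Raw (unstandardized) variables are used so coefficients are on
#' the delta-gamma-per-unit-factor scale.
#'
#' @param data tibble with columns `delta_gamma`, `kext`, `krec` (e.g. the
#'   output of [run_grid()]).
#' @return object of class `dg_regression`; see `tidy()` and `glance()`.
#' @export
fit_delta_gamma_regression <- function(data) {
  stopifnot(all(c("delta_gamma", "kext", "krec") %in% names(data)))
  fit <- lm(delta_gamma ~ kext + krec, data = data)
  if (any(is.na(coef(fit)))) abort("rank-deficient design (constant predictor?)")
  structure(list(fit = fit, n = nrow(data)), class = "dg_regression")
}

#' @export
tidy.dg_regression <- function(x, conf.level = 0.95, ...) {
  s <- summary(x$fit)$coefficients
  ci <- confint(x$fit, level = conf.level)
  tibble(
    term = rownames(s),
    estimate = unname(s[, 1]), std.error = unname(s[, 2]),
    statistic = unname(s[, 3]), p.value = unname(s[, 4]),
    conf.low = unname(ci[, 1]), conf.high = unname(ci[, 2])
  )
}

#' @export
glance.dg_regression <- function(x, ...) {
  s <- summary(x$fit)
  tibble(r.squared = s$r.squared, adj.r.squared = s$adj.r.squared,
         sigma = s$sigma, nobs = x$n)
}

#' @export
print.dg_regression <- function(x, ...) {
  cat("Linear model: delta_gamma ~ kext + krec  (n =", x$n, ")\n\n")
  print(as.data.frame(tidy(x)), digits = 3, row.names = FALSE)
  g <- glance(x)
  cat(sprintf("\nR2 = %.3f, adjusted R2 = %.3f\n", g$r.squared, g$adj.r.squared))
  invisible(x)
}

#' Linear causal mediation analysis with bootstrap intervals
#'
#' Fits the mediator model `M ~ X` and outcome model `Y ~ X + M` by least
#' squares and reports the average causally mediated effect (ACME = a*b),
#' average direct effect (ADE = c'), total effect (TE = ACME + ADE, an exact
#' identity for linear models) and proportion mediated (ACME/TE), with
#' nonparametric percentile bootstrap confidence intervals and p-values.
#' Variables are z-scored first by default, matching the convention of
#' standardizing each variable before mediation.
#'
#' @param data data frame containing the three variables.
#' @param x,m,y column names of treatment, mediator and outcome.
#' @param n_boot bootstrap resamples.
#' @param conf.level interval coverage.
#' @param scale standardize the three columns first (default TRUE).
#' @param seed integer seed for the bootstrap (isolated from the global RNG).
#' @return object of class `ca3_mediation`; `tidy()` returns the estimate
#'   table.
#' @export
mediation_analysis <- function(data, x = "kext", m = "pyr_rate",
                               y = "lfp_gamma", n_boot = 1000,
                               conf.level = 0.95, scale = TRUE, seed = 1L) {
  d <- tibble(X = data[[x]], M = data[[m]], Y = data[[y]])
  if (anyNA(d)) d <- d[complete.cases(d), ]
  if (nrow(d) < 10) abort("mediation needs at least 10 complete rows")
  for (cl in names(d)) {
    if (sd(d[[cl]]) == 0) abort(paste0("zero-variance column: ", cl))
  }
  if (scale) d <- standardize(d)

  point <- med_paths(d)
  idx <- withr::with_seed(as.integer(seed), {
    matrix(sample.int(nrow(d), nrow(d) * n_boot, replace = TRUE),
           nrow = n_boot)
  })
  boots <- matrix(NA_real_, n_boot, 4,
                  dimnames = list(NULL, c("acme", "ade", "te", "prop")))
  for (b in seq_len(n_boot)) {
    boots[b, ] <- unlist(med_paths(d[idx[b, ], ]))
  }
  alpha <- 1 - conf.level
  est <- tibble(
    term = c("acme", "ade", "total_effect", "prop_mediated"),
    estimate = unname(unlist(point)),
    conf.low = apply(boots, 2, quantile, alpha / 2, na.rm = TRUE),
    conf.high = apply(boots, 2, quantile, 1 - alpha / 2, na.rm = TRUE),
    p.value = apply(boots, 2, function(v) {
      v <- v[is.finite(v)]
      p <- 2 * min(mean(v <= 0), mean(v >= 0))
      max(p, 1 / length(v))
    })
  )
  structure(list(estimates = est, n = nrow(d), n_boot = n_boot,
                 x = x, m = m, y = y),
            class = "ca3_mediation")
}

med_paths <- function(d) {
  a <- coef(lm(M ~ X, data = d))[["X"]]
  fy <- coef(lm(Y ~ X + M, data = d))
  acme <- a * fy[["M"]]
  ade <- fy[["X"]]
  te <- acme + ade
  list(acme = acme, ade = ade, te = te,
       prop = if (te != 0) acme / te else NA_real_)
}

#' @export
tidy.ca3_mediation <- function(x, ...) x$estimates

#' @export
glance.ca3_mediation <- function(x, ...) {
  tibble(nobs = x$n, n_boot = x$n_boot,
         prop_mediated = x$estimates$estimate[4])
}

#' @export
print.ca3_mediation <- function(x, ...) {
  cat(sprintf("Mediation analysis: %s -> %s -> %s  (n = %d, %d bootstrap resamples)\n\n",
              x$x, x$m, x$y, x$n, x$n_boot))
  print(as.data.frame(x$estimates), digits = 3, row.names = FALSE)
  invisible(x)
}
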