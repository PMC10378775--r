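d7h_model <- function() itc_model(N = c(0.35, 1), Ka = c(48e4, 2.3e4),
                                  dH = c(-8.0, -10.3))
e11a_model <- function() itc_model(N = 1.1, Ka = 2.1e4, dH = -8.7)

test_that("noise-free curves are recovered to better than 0.1%", {
  ## one site
  curve1 <- itc_simulate(e11a_model(), itc_protocol())
  cf1 <- coef(itc_fit(curve1, n_sites = 1, n_boot = 0))
  expect_equal(cf1["site1", "N"], 1.1, tolerance = 1e-3)
  expect_equal(cf1["site1", "Ka"], 2.1e4, tolerance = 1e-3)
  expect_equal(cf1["site1", "dH"], -8.7, tolerance = 1e-3)
  ## two sites
  curve2 <- itc_simulate(d7h_model(), itc_protocol())
  cf2 <- coef(itc_fit(curve2, n_sites = 2, n_boot = 0))
  expect_equal(cf2["high", "N"], 0.35, tolerance = 1e-3)
  expect_equal(cf2["high", "Ka"], 48e4, tolerance = 1e-3)
  expect_equal(cf2["low", "N"], 1, tolerance = 1e-3)
  expect_equal(cf2["low", "Ka"], 2.3e4, tolerance = 1e-3)
  expect_equal(cf2["low", "dH"], -10.3, tolerance = 1e-3)
})

test_that("site-count selection separates one- and two-site chemistry", {
  suppressWarnings({
    ## a single-site mutant-like curve selects one site
    s1 <- synth_itc(e11a_model(), itc_protocol(), 0.02, seed = 2)
    expect_equal(as.integer(select_n_sites(s1$curve)), 1L)
    ## the intact two-site curve selects two sites (demonstrated at 1%
    ## noise: at 2% of the maximum heat the 20-injection protocol barely
    ## resolves the high-affinity shoulder against the AICc parsimony term)
    for (seed in 1:3) {
      s2 <- synth_itc(d7h_model(), itc_protocol(), 0.01, seed = seed)
      expect_equal(as.integer(select_n_sites(s2$curve)), 2L)
    }
  })
  ## a flat, signal-free curve is flagged indeterminate
  flat <- itc_simulate(itc_model(1, 1e4, 0), itc_protocol())
  expect_error(select_n_sites(flat), "no heat signal")
})

test_that("overfitting a one-site curve collapses the redundant site class", {
  suppressWarnings({
    s <- synth_itc(e11a_model(), itc_protocol(), 0.01, seed = 5)
    f2 <- itc_fit(s$curve, n_sites = 2, n_boot = 0)
    f1 <- itc_fit(s$curve, n_sites = 1, n_boot = 0)
    cf <- coef(f2)
    ## one class vanishes (tiny N), duplicates the other (degenerate Ka
    ## ratio) or runs to negligible affinity at the box bound
    collapse <- min(cf[, "N"]) < 0.05 ||
      abs(log10(cf["high", "Ka"] / cf["low", "Ka"])) < 0.5 ||
      min(cf[, "Ka"]) <= 100
    expect_true(collapse)
    ## and the information criterion prefers the one-site model
    expect_lt(f1$aicc, f2$aicc + 2)
  })
})

test_that("bootstrap uncertainties and model methods behave", {
  suppressWarnings({
    s <- synth_itc(e11a_model(), itc_protocol(), 0.02, seed = 9)
    f <- itc_fit(s$curve, n_sites = 1, n_boot = 30, seed = 4)
  })
  expect_false(is.null(f$bootstrap))
  expect_true(all(f$bootstrap$sd >= 0))
  v <- vcov(f)
  expect_equal(dim(v), c(3L, 3L))
  expect_true(all(diag(v) >= 0))
  ## residuals + fitted reconstruct the data
  expect_equal(fitted(f) + residuals(f), s$curve$heat)
  ## predict returns the model-implied curve for the training protocol
  pr <- predict(f)
  expect_s3_class(pr, "itc_curve")
  expect_equal(pr$heat, fitted(f), tolerance = 1e-9)
  ## parametric simulation is reproducible under a seed
  s1 <- simulate(f, nsim = 2, seed = 1)
  s2 <- simulate(f, nsim = 2, seed = 1)
  expect_equal(s1, s2)
  ## print methods run
  expect_output(print(f), "ITC fit")
  expect_output(print(summary(f)), "AICc")
})

test_that("fitting guards reject unusable inputs", {
  prot <- itc_protocol(injection_volumes_ul = rep(2, 6))
  short <- itc_simulate(d7h_model(), prot)
  expect_error(itc_fit(short, n_sites = 1, n_boot = 0), "at least 8")
  curve <- itc_simulate(d7h_model(), itc_protocol())
  attr(curve, "protocol") <- NULL
  expect_error(itc_fit(curve, n_sites = 1, n_boot = 0), "protocol")
})
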