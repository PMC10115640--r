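test_that("a constant trace yields one dwell censored at both ends", {
  p <- make_path("A", 30)
  d <- extract_dwells(p)
  expect_equal(nrow(d), 1L)
  expect_equal(d$dwell_s, 30)
  expect_true(all(d$censored))
})

test_that("dwells of a known alternating path match the generator exactly", {
  dw <- c(1.2, 0.4, 2.5, 0.9, 3.1)
  p <- make_path(c("A", "B", "A", "B", "A"), dw)
  d <- extract_dwells(p)
  expect_equal(d$dwell_s, dw, tolerance = 1e-12)
  expect_equal(d$censored, c(TRUE, FALSE, FALSE, FALSE, TRUE))
  # dwell conservation under any aggregate partition
  d2 <- extract_dwells(p, aggregate_map = c(A = "x", B = "x"))
  expect_equal(sum(d2$dwell_s), sum(dw), tolerance = 1e-12)
})

test_that("bridging merges sub-threshold gaps into the surrounding sojourn", {
  p <- make_path(c("B", "A", "B", "A", "B"), c(0.1, 0.005, 0.1, 0.05, 0.2),
                 classes = data.frame(name = c("A", "B"),
                                      fret_class = c("low", "high"),
                                      pore_conducting = c(FALSE, TRUE)))
  d <- extract_dwells(p, aggregate_map = c(A = "closed", B = "open"),
                      bridge_s = 0.01, bridge_class = "open")
  opens <- d$dwell_s[d$class == "open"]
  expect_equal(sort(opens), c(0.2, 0.205), tolerance = 1e-12)
  expect_equal(sum(d$dwell_s), 0.455, tolerance = 1e-12)
})

test_that("censored single-exponential ML estimate hits a known rate", {
  set.seed(3)
  n <- 5000
  td <- rexp(n, 2)
  f <- fit_survival(td, n_components = 1L)
  se <- 2 / sqrt(n)
  expect_lt(abs(f$rates_per_s - 2), 3 * se)
  # censoring handled: censored dwells contribute exposure, not events
  cen <- data.frame(dwell_s = c(td, rep(3, 500)),
                    censored = rep(c(FALSE, TRUE), c(n, 500)))
  f2 <- fit_survival(cen, n_components = 1L)
  expect_equal(f2$rates_per_s, n / sum(cen$dwell_s), tolerance = 1e-10)
})

test_that("two-component mixtures are recovered within 15%", {
  set.seed(8)
  n <- 5000
  comp <- rbinom(n, 1, 0.3)
  td <- ifelse(comp == 1, rexp(n, 1 / 2), rexp(n, 1 / 0.2))
  f <- suppressWarnings(fit_survival(td, n_components = 2L))
  expect_equal(f$taus_s[1], 0.2, tolerance = 0.15)
  expect_equal(f$taus_s[2], 2.0, tolerance = 0.15)
  expect_equal(f$weights[1], 0.7, tolerance = 0.15)
})

test_that("BIC prefers one component on single-exponential data", {
  wins <- 0L
  for (s in 1:100) {
    set.seed(s)
    td <- rexp(300, 1.5)
    b1 <- fit_survival(td, 1L)$bic
    b2 <- suppressWarnings(fit_survival(td, 2L))$bic
    wins <- wins + (b1 <= b2)
  }
  expect_gte(wins, 95L)
})

test_that("survival fitting validates its input", {
  expect_error(fit_survival(rep(1, 100)), "degenerate")
  expect_error(fit_survival(c(-1, 2)), "positive")
  expect_warning(fit_survival(rexp(30, 1), 1L), "uncensored dwells")
})

test_that("dwell means below three frames trigger the time-averaging warning", {
  set.seed(2)
  td <- rexp(500, 10)   # mean 0.1 s
  expect_warning(fit_survival(td, 1L, frame_s = 0.1), "time averaging")
  expect_silent(fit_survival(td, 1L, frame_s = 0.01))
})

test_that("Hill fit is exact on its own model and scale-equivariant", {
  dose <- 10^seq(-6, -3, length.out = 9)
  y <- dose / (dose + 1e-4)
  f <- fit_hill(dose, y)
  expect_equal(f$ec50_M, 1e-4, tolerance = 1e-9)
  expect_lt(max(abs(f$residuals)), 1e-12)
  expect_equal(f$hill_n, 1)
  f10 <- fit_hill(dose * 10, y)
  expect_equal(f10$ec50_M, 10 * f$ec50_M, tolerance = 1e-9)
})

test_that("noisy Hill estimates are unbiased at the stated replication", {
  dose <- 10^seq(-6, -3, length.out = 8)
  truth <- dose / (dose + 5e-5)
  est <- vapply(1:500, function(s) {
    set.seed(s)
    fit_hill(dose, pmax(truth + rnorm(8, 0, 0.02), 0))$ec50_M
  }, numeric(1))
  expect_equal(mean(est), 5e-5, tolerance = 0.05)
})

test_that("Hill fit flags curves without a midpoint in range", {
  dose <- 10^seq(-6, -5, length.out = 5)
  y <- dose / (dose + 1e-3)   # midpoint far above the dose range
  f <- fit_hill(dose, y)
  expect_equal(f$flag, "no_curvature")
})

test_that("relaxation fits recover exact constants and select by BIC", {
  t <- seq(0, 5, 0.01)
  f1 <- fit_relaxation(t, exp(-t / 0.49), n_components = 1L)
  expect_equal(f1$taus_s, 0.49, tolerance = 1e-6)
  t2 <- seq(0, 100, 0.1)
  y2 <- 0.6 * exp(-t2 / 1.6) + 0.4 * exp(-t2 / 20)
  f2 <- fit_relaxation(t2, y2, n_components = 2L)
  expect_equal(f2$taus_s, c(1.6, 20), tolerance = 0.02)
  expect_equal(f2$amplitudes, c(0.6, 0.4), tolerance = 0.02)
  # BIC selection picks two components here and one for a pure decay
  expect_equal(fit_relaxation(t2, y2)$n_components, 2L)
  expect_equal(fit_relaxation(t, exp(-t / 0.5))$n_components, 1L)
})

test_that("transition frequency counts class switches per analyzable time", {
  p <- make_path(rep(c("A", "B"), 6)[1:11], rep(c(12, 8), 6)[1:11])
  tf <- transition_frequency(p)
  expect_equal(tf$per_trace$switches, 10L)
  expect_equal(tf$pooled, 10 / sum(rep(c(12, 8), 6)[1:11]), tolerance = 1e-12)
  # constant trace
  expect_equal(transition_frequency(make_path("A", 100))$pooled, 0)
})
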