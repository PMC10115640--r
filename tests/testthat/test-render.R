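test_that("noiseless rendering reproduces emission means exactly", {
  # dwells much longer than the frame: piecewise-constant FRET at the means
  p <- make_path(c("A", "B", "A"), c(2, 3, 2))
  em <- clean_emission()
  tr <- render_fret_trace(p, em, seed = 1)
  ef <- tr$acceptor / (tr$acceptor + tr$donor)
  expect_equal(ef[1:20], rep(em$fret_means[["low"]], 20), tolerance = 1e-12)
  expect_equal(ef[21:50], rep(em$fret_means[["high"]], 30), tolerance = 1e-12)
  # frame-average identity over every full dwell
  expect_equal(mean(ef[51:70]), em$fret_means[["low"]], tolerance = 1e-12)
})

test_that("sub-frame excursions time-average to the dwell-weighted value", {
  # a 5 ms high-FRET dwell inside a 100 ms frame on a low background
  p <- make_path(c("A", "B", "A"), c(0.050, 0.005, 0.245))
  em <- clean_emission()
  tr <- render_fret_trace(p, em, seed = 1)
  ef <- tr$acceptor[1] / (tr$acceptor[1] + tr$donor[1])
  lo <- em$fret_means[["low"]]; hi <- em$fret_means[["high"]]
  expected <- (0.050 * lo + 0.005 * hi + 0.045 * lo) / 0.1
  expect_equal(ef, expected, tolerance = 1e-12)
  expect_gt(ef, lo); expect_lt(ef, hi)
})

test_that("realized signal-to-noise ratio tracks the requested value", {
  p <- make_path("A", 60)
  em <- emission_model(blink_rate_per_s = 0, donor_bleach_mean_s = Inf)
  tr <- render_fret_trace(p, em, seed = 4)
  total <- tr$donor + tr$acceptor
  snr <- mean(total) / stats::sd(total)
  expect_equal(snr, cftrgate:::.emission_snr(em), tolerance = 0.1)
})

test_that("photobleaching is a single step silencing both channels", {
  p <- make_path("B", 60)
  em <- emission_model(donor_bleach_mean_s = 20, blink_rate_per_s = 0,
                       intensity_noise_sd = 0)
  tr <- render_fret_trace(p, em, seed = 8)
  truth <- attr(tr, "truth")
  b <- attr(tr, "bleach_s")
  expect_true(is.finite(b) && b < 60)
  post <- which(tr$time_s > b + 0.1)
  expect_true(all(truth$visible_frac[post] == 0))
  expect_true(all(abs(tr$donor[post]) < 1e-9))
  expect_true(all(abs(tr$acceptor[post]) < 1e-9))
})

test_that("rendering is bit-reproducible for identical seeds", {
  p <- make_path(c("A", "B"), c(5, 5))
  em <- emission_model()
  expect_identical(render_fret_trace(p, em, seed = 3),
                   render_fret_trace(p, em, seed = 3))
  expect_false(identical(render_fret_trace(p, em, seed = 3)$donor,
                         render_fret_trace(p, em, seed = 4)$donor))
})

test_that("a never-conducting path renders as baseline current", {
  p <- make_path("A", 10)
  tr <- render_current_trace(p, amplitude_pA = 0.5, noise_sd = 0.1, seed = 2)
  expect_lt(abs(mean(tr$pA)), 0.01)
  # low-pass filtering shrinks the white-noise sd
  expect_lt(stats::sd(tr$pA), 0.1)
  expect_gt(stats::sd(tr$pA), 0)
})

test_that("a long opening produces two current levels an amplitude apart", {
  p <- make_path(c("A", "B", "A"), c(2, 1, 2),
                 classes = data.frame(name = c("A", "B"),
                                      fret_class = c("low", "high"),
                                      pore_conducting = c(FALSE, TRUE)))
  tr <- render_current_trace(p, amplitude_pA = 0.6, noise_sd = 0.05, seed = 2)
  open_lvl <- stats::median(tr$pA[tr$time_s > 2.1 & tr$time_s < 2.9])
  closed_lvl <- stats::median(tr$pA[tr$time_s < 1.9])
  expect_equal(open_lvl - closed_lvl, 0.6, tolerance = 0.05)
})

test_that("2 ms flickers are incompletely resolved at 100 Hz filtering", {
  p <- make_path(c("B", "A", "B"), c(1, 0.002, 1),
                 classes = data.frame(name = c("A", "B"),
                                      fret_class = c("low", "high"),
                                      pore_conducting = c(FALSE, TRUE)))
  tr <- render_current_trace(p, amplitude_pA = 1, noise_sd = 0, seed = 1)
  dip <- min(tr$pA[tr$time_s > 0.9 & tr$time_s < 1.2])
  # the deflection toward zero covers less than half the amplitude
  expect_gt(dip, 0.5)
})

test_that("current rendering validates its arguments", {
  p <- make_path("A", 1)
  expect_error(render_current_trace(p, amplitude_pA = 0), "positive")
  expect_error(render_current_trace(p, sample_hz = 500, filter_hz = 100),
               "10 \\* filter_hz")
})

test_that("ensembles are deterministic and delegate to the renderers", {
  g <- build_topology("WT")
  pr <- steady_protocol(3e-3, 20)
  e1 <- generate_ensemble(g, pr, 3, seed = 6)
  e2 <- generate_ensemble(g, pr, 3, seed = 6)
  expect_identical(e1$traces, e2$traces)
  expect_equal(length(e1$traces), 3L)
  expect_equal(e1$metadata$variant, "WT")
})

test_that("dephosphorylated apo ensembles show no class transitions", {
  g <- build_topology("WT")
  pr <- protocol(0, 30, phosphorylated = FALSE)
  ens <- generate_ensemble(g, pr, 5, seed = 12)
  for (tr in ens$traces) {
    truth <- attr(tr, "truth")
    expect_true(all(truth$fret_class == "low"))
  }
})

test_that("ensemble truth high-FRET fraction matches the stationary solve", {
  g <- build_topology("WT")
  ens <- generate_ensemble(g, steady_protocol(3e-3, 60), 120, seed = 15)
  frac <- vapply(ens$paths, function(p) {
    ct <- attr(p, "state_classes")
    hi <- ct$fret_class[match(p$state, ct$name)] == "high"
    sum(p$dwell_s[hi]) / sum(p$dwell_s)
  }, numeric(1))
  pdim <- stationary_distribution(g, 3e-3)$pdim
  expect_lt(abs(mean(frac) - pdim), 3 * stats::sd(frac) / sqrt(length(frac)))
})
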