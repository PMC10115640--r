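test_that("noiseless two-level series segments exactly", {
  x <- c(rep(0.25, 40), rep(0.49, 30), rep(0.25, 30))
  id <- skm_idealize(x, skm_model())
  expect_equal(id$label, rep(c("low", "high", "low"), c(40, 30, 30)))
  mu <- attr(id, "means")
  expect_equal(mu, c(0.25, 0.49), tolerance = 1e-12)
  expect_true(attr(id, "converged"))
})

test_that("the segmentation objective never decreases across iterations", {
  set.seed(21)
  x <- rep(rep(c(0.28, 0.49), times = c(20, 30)), 5) + rnorm(250, 0, 0.05)
  id <- skm_idealize(x, skm_model())
  ll <- attr(id, "loglik_trace")
  expect_gte(length(ll), 2L)
  expect_true(all(diff(ll) >= -1e-8))
})

test_that("frame labels recover a known truth path at realistic noise", {
  g <- build_topology("WT")
  ens <- generate_ensemble(g, steady_protocol(3e-3, 60), 12, seed = 31)
  acc <- n_tot <- 0
  for (i in seq_along(ens$traces)) {
    tr <- ens$traces[[i]]
    truth <- attr(tr, "truth")
    ef <- compute_fret(tr)
    id <- skm_idealize(ef, skm_model())
    ok <- !is.na(id$state) & truth$visible_frac > 0.99
    lab_true <- ifelse(truth$fret_class == "high", "high", "low")
    acc <- acc + sum(id$label[ok] == lab_true[ok])
    n_tot <- n_tot + sum(ok)
  }
  expect_gt(n_tot, 2000)
  expect_gt(acc / n_tot, 0.95)
})

test_that("idealization is deterministic and flags dark frames", {
  set.seed(5)
  x <- c(rnorm(100, 0.28, 0.05), rep(NA, 10), rnorm(100, 0.49, 0.05))
  id1 <- skm_idealize(x, skm_model())
  id2 <- skm_idealize(x, skm_model())
  expect_identical(id1, id2)
  expect_true(all(id1$label[101:110] == "dark"))
  expect_error(skm_idealize(rep(NA_real_, 50), skm_model()), "usable")
})

test_that("unresolvably close states merge into one", {
  set.seed(9)
  x <- rnorm(400, 0.37, 0.05)
  id <- skm_idealize(x, skm_model())
  expect_true(attr(id, "merged"))
  occ <- attr(id, "occupancy")
  mu <- attr(id, "means")
  expect_equal(mu[which.max(occ)], mean(x), tolerance = 1e-9)
  expect_equal(max(occ), 1)
})

test_that("idealized occupancy converges to generator truth as noise shrinks", {
  g <- build_topology("WT")
  pr <- steady_protocol(3e-3, 60)
  em <- emission_model(intensity_noise_sd = 5, blink_rate_per_s = 0,
                       donor_bleach_mean_s = Inf)   # FRET sd ~ 0.01
  ens <- generate_ensemble(g, pr, 25, em, seed = 41)
  high_est <- high_true <- 0
  for (i in seq_along(ens$traces)) {
    id <- skm_idealize(compute_fret(ens$traces[[i]]), skm_model())
    high_est <- high_est + sum(id$label == "high")
    truth <- attr(ens$traces[[i]], "truth")
    high_true <- high_true + sum(truth$fret_class == "high")
  }
  n <- sum(vapply(ens$traces, nrow, numeric(1)))
  expect_lt(abs(high_est / n - high_true / n), 0.01)
})

test_that("ensemble histograms are normalized with per-group errors", {
  set.seed(13)
  frets <- lapply(1:6, function(i)
    data.frame(fret = rnorm(300, 0.49, 0.05), dark = FALSE))
  h <- ensemble_histogram(frets, groups = rep(1:3, each = 2))
  expect_equal(h$n_groups, 3L)
  expect_equal(sum(h$density_mean) * 0.02, 1, tolerance = 0.01)
  expect_true(all(is.finite(h$density_se)))
  expect_lt(abs(h$bin_mid[which.max(h$density_mean)] - 0.49), 0.03)
  expect_error(ensemble_histogram(frets, groups = c(1, 1, 1, 2, 2, NA)))
  # delta-like noiseless ensemble occupies a single bin
  h1 <- ensemble_histogram(list(data.frame(fret = rep(0.25, 100), dark = FALSE)))
  expect_equal(sum(h1$density_mean > 0), 1L)
})
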