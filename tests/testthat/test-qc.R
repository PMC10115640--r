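# Synthetic trace builder with controllable defects (deterministic noise).
fake_trace <- function(n = 600, level = 500, fret = 0.4, bleach_at = 400,
                       blinks = integer(0), blink_len = 4L,
                       noise = 10, second_step_at = NA, high_tail = 0,
                       seed = 1, id = "fx") {
  set.seed(seed)
  total <- rep(level, n)
  if (!is.na(second_step_at))
    total[second_step_at:n] <- level / 2
  if (bleach_at < n) total[(bleach_at + 1L):n] <- 0
  e <- rep(fret, n)
  if (high_tail > 0) {
    hi_idx <- seq_len(round(high_tail * bleach_at))
    e[hi_idx] <- 0.9
  }
  acceptor <- total * e + stats::rnorm(n, 0, noise)
  donor <- total * (1 - e) + stats::rnorm(n, 0, noise)
  for (b in blinks) {
    idx <- b:(b + blink_len - 1L)
    acceptor[idx] <- stats::rnorm(blink_len, 0, noise)
    donor[idx] <- stats::rnorm(blink_len, 0, noise)
  }
  structure(data.frame(frame = seq_len(n), time_s = (seq_len(n) - 0.5) * 0.1,
                       donor = donor, acceptor = acceptor),
            class = c("fret_trace", "data.frame"),
            trace_id = id, frame_s = 0.1)
}

test_that("compute_fret implements the intensity ratio with dark flagging", {
  tr <- data.frame(donor = c(100, 300, 0, 0), acceptor = c(100, 100, 200, 0))
  ef <- compute_fret(tr, dark_threshold = 10)
  expect_equal(ef$fret[1], 0.5)
  expect_equal(ef$fret[2], 0.25)
  expect_equal(ef$fret[3], 1.0)
  expect_true(is.na(ef$fret[4]) && ef$dark[4])
  expect_true(all(ef$fret[1:3] >= 0 & ef$fret[1:3] <= 1))
  expect_error(compute_fret(data.frame(donor = 1:3, acceptor = 1:2)))
})

test_that("clean traces pass and each defect trips its criterion", {
  qc1 <- qc_select(list(fake_trace()), qc_criteria())
  expect_true(qc1$accepted)
  cases <- list(
    list(tr = fake_trace(second_step_at = 200, seed = 2), reason = "multi_step_bleach"),
    list(tr = fake_trace(bleach_at = 600, seed = 3), reason = "no_single_step_bleach"),
    list(tr = fake_trace(blinks = c(50, 100, 150, 200, 250), seed = 4),
         reason = "too_many_blinks"),
    list(tr = fake_trace(noise = 60, seed = 5), reason = "low_snr"),
    list(tr = fake_trace(bleach_at = 30, seed = 6),
         reason = "too_few_frames_above_baseline"),
    list(tr = fake_trace(high_tail = 0.5, seed = 7), reason = "fret_above_max"))
  for (cs in cases) {
    qc <- qc_select(list(cs$tr), qc_criteria())
    expect_false(qc$accepted)
    expect_equal(qc$report$reason, cs$reason)
  }
})

test_that("defect-injected ensembles are separated exactly from clean ones", {
  # defects exceed their thresholds at least two-fold
  clean <- lapply(1:20, function(i) fake_trace(seed = i, id = sprintf("c%02d", i)))
  bad <- c(
    lapply(1:4, function(i) fake_trace(blinks = 40 * (1:8), seed = 100 + i,
                                       id = sprintf("b%02d", i))),       # 8 blinks
    lapply(1:4, function(i) fake_trace(noise = 70, seed = 200 + i,
                                       id = sprintf("n%02d", i))),       # SNR ~ 5
    lapply(1:4, function(i) fake_trace(second_step_at = 150, seed = 300 + i,
                                       id = sprintf("s%02d", i))))       # 2 steps
  qc <- qc_select(c(clean, bad), qc_criteria())
  expect_identical(qc$accepted, rep(c(TRUE, FALSE), c(20, 12)))
})

test_that("QC is order-stable under permutation of the ensemble", {
  traces <- c(lapply(1:6, function(i) fake_trace(seed = i, id = paste0("a", i))),
              lapply(1:3, function(i) fake_trace(noise = 60, seed = 10 + i,
                                                 id = paste0("z", i))))
  qc <- qc_select(traces, qc_criteria())
  set.seed(99)
  perm <- sample(length(traces))
  qc_p <- qc_select(traces[perm], qc_criteria())
  expect_identical(qc_p$accepted, qc$accepted[perm])
  expect_setequal(qc_p$report$trace_id[qc_p$accepted],
                  qc$report$trace_id[qc$accepted])
})

test_that("unevaluable traces are rejected with the dedicated reason", {
  tiny <- fake_trace(n = 6)
  qc <- qc_select(list(tiny), qc_criteria())
  expect_false(qc$accepted)
  expect_equal(qc$report$reason, "unevaluable")
})
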