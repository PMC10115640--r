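test_that("an absorbing start state yields a single full-length segment", {
  g <- two_state_graph(0, 1)   # A has no outflow
  p <- simulate_ssa(g, steady_protocol(1e-3, 50), seed = 1, start_state = "A")
  expect_equal(nrow(p), 1L)
  expect_equal(p$state, "A")
  expect_equal(p$dwell_s, 50)
})

test_that("segments tile the duration and consecutive states differ", {
  g <- build_topology("WT")
  p <- simulate_ssa(g, steady_protocol(3e-3, 100), seed = 3)
  expect_equal(sum(p$dwell_s), 100, tolerance = 1e-9)
  expect_equal(p$entry_s[1], 0)
  expect_lt(max(abs(p$entry_s[-1] - (p$entry_s + p$dwell_s)[-nrow(p)])), 1e-9)
  expect_true(all(p$state[-1] != p$state[-nrow(p)]))
})

test_that("identical graph, protocol and seed give identical paths", {
  g <- build_topology("WT")
  pr <- steady_protocol(3e-3, 50)
  p1 <- simulate_ssa(g, pr, seed = 42)
  p2 <- simulate_ssa(g, pr, seed = 42)
  expect_identical(p1, p2)
  p3 <- simulate_ssa(g, pr, seed = 43)
  expect_false(identical(p1$dwell_s, p3$dwell_s))
})

test_that("empirical mean dwells match exponential expectations", {
  g <- two_state_graph(2, 1)
  p <- simulate_ssa(g, steady_protocol(1e-3, 3000), seed = 5, start_state = "A")
  da <- p$dwell_s[p$state == "A"]
  db <- p$dwell_s[p$state == "B"]
  # drop the (censored) last segment
  da <- da[-length(da)]
  expect_gt(length(da), 1500)
  expect_lt(abs(mean(da) - 0.5), 3 * stats::sd(da) / sqrt(length(da)))
  expect_lt(abs(mean(db[-length(db)]) - 1.0),
            3 * stats::sd(db) / sqrt(length(db) - 1))
})

test_that("per-state dwells are exponential with rate = total outflow", {
  g <- two_state_graph(2, 1)
  p <- simulate_ssa(g, steady_protocol(1e-3, 8000), seed = 11, start_state = "A")
  da <- p$dwell_s[p$state == "A"]
  da <- da[-length(da)]
  expect_gt(length(da), 5000)
  ks <- suppressWarnings(stats::ks.test(da, "pexp", rate = 2))
  expect_gt(ks$p.value, 0.01)
})

test_that("long-run SSA time fractions match the stationary solve", {
  for (seed in c(2, 7)) {
    g <- random_graph(seed)
    pi_exact <- stationary_distribution(g, 1e-3)$occupancy
    p <- simulate_ssa(g, steady_protocol(1e-3, 4000), seed = seed + 100)
    # standard errors from 20 block means of the occupancy of each state
    edges <- seq(0, 4000, length.out = 21L)
    frac_block <- sapply(seq_len(20L), function(b) {
      lo <- edges[b]; hi <- edges[b + 1L]
      ov <- pmax(pmin(p$entry_s + p$dwell_s, hi) - pmax(p$entry_s, lo), 0)
      tapply(ov, factor(p$state, levels = g$states$name), sum) / (hi - lo)
    })
    frac_block[is.na(frac_block)] <- 0
    est <- rowMeans(frac_block)
    se <- apply(frac_block, 1L, stats::sd) / sqrt(20)
    expect_true(all(abs(est - pi_exact) <= 3 * pmax(se, 1e-4)))
  }
})

test_that("hydrolysis events are the OPEN_pre to OPEN_post firings", {
  g <- build_topology("WT")
  p <- simulate_ssa(g, steady_protocol(3e-3, 300), seed = 9)
  hyd <- hydrolysis_events(p)
  n_fire <- sum(p$state[-nrow(p)] == "OPEN_pre" & p$state[-1] == "OPEN_post")
  expect_equal(length(hyd), n_fire)
  expect_gt(length(hyd), 0)
  expect_true(all(diff(hyd) > 0))
})

test_that("ATP withdrawal mid-protocol leaves the chain to be absorbed apo", {
  g <- build_topology("WT")
  pr <- protocol(data.frame(start_s = c(0, 20), atp_molar = c(3e-3, 0)), 400)
  p <- simulate_ssa(g, pr, seed = 21, start_state = "DIM_closed")
  expect_equal(sum(p$dwell_s), 400, tolerance = 1e-9)
  # final state after long ATP-free chase is the apo separated state
  expect_equal(p$state[nrow(p)], "SEP_apo")
  # and the apo dwell runs to the end of the record
  expect_gt(p$dwell_s[nrow(p)], 100)
})

test_that("state path round-trips through CSV with its sidecar", {
  g <- build_topology("WT")
  p <- simulate_ssa(g, steady_protocol(3e-3, 20), seed = 2)
  f <- file.path(tempdir(), "path.csv")
  write_state_path(p, f)
  p2 <- read_state_path(f)
  expect_equal(as.data.frame(p2)[, c("state", "entry_s", "dwell_s")],
               as.data.frame(p)[, c("state", "entry_s", "dwell_s")],
               tolerance = 1e-12)
  expect_true(file.exists(sub("\\.csv$", ".json", f)))
  unlink(c(f, sub("\\.csv$", ".json", f)))
})
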