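# Small reference graphs used across tests.

# Two-state toy: A <-> B with rates k_ab, k_ba (neither ATP-dependent).
two_state_graph <- function(k_ab = 1, k_ba = 1,
                            open = 2L, dimer = 2L) {
  states <- data.frame(name = c("A", "B"),
                       pore_conducting = c(FALSE, TRUE),
                       fret_class = c("low", "high"),
                       stringsAsFactors = FALSE)
  edges <- data.frame(from = c("A", "B"), to = c("B", "A"),
                      rate = c("k_ab", "k_ba"), stringsAsFactors = FALSE)
  state_graph(states, edges, c(k_ab = k_ab, k_ba = k_ba),
              open_set = open, dimer_set = dimer)
}

# Unidirectional n-state cycle with the given rates.
cycle_graph <- function(rates_vec) {
  n <- length(rates_vec)
  nm <- paste0("S", seq_len(n))
  states <- data.frame(name = nm,
                       pore_conducting = rep(FALSE, n),
                       fret_class = rep("low", n),
                       stringsAsFactors = FALSE)
  rn <- paste0("r", seq_len(n))
  edges <- data.frame(from = nm, to = nm[c(2:n, 1L)], rate = rn,
                      stringsAsFactors = FALSE)
  state_graph(states, edges, stats::setNames(rates_vec, rn),
              open_set = integer(), dimer_set = integer())
}

# Random irreducible graph with <= n_max states: a random cycle plus
# random extra edges, rates log-uniform in [0.1, 10].
random_graph <- function(seed, n_max = 10L) {
  set.seed(seed)
  n <- sample(3:n_max, 1L)
  nm <- paste0("S", seq_len(n))
  from <- nm
  to <- nm[c(2:n, 1L)]
  n_extra <- sample(1:(2L * n), 1L)
  ef <- sample(nm, n_extra, replace = TRUE)
  et <- sample(nm, n_extra, replace = TRUE)
  keep <- ef != et
  from <- c(from, ef[keep])
  to <- c(to, et[keep])
  rn <- paste0("r", seq_along(from))
  rates <- stats::setNames(10^stats::runif(length(from), -1, 1), rn)
  states <- data.frame(name = nm, pore_conducting = rep(FALSE, n),
                       fret_class = rep("low", n), stringsAsFactors = FALSE)
  edges <- data.frame(from = from, to = to, rate = rn,
                      stringsAsFactors = FALSE)
  state_graph(states, edges, rates,
              open_set = integer(), dimer_set = integer())
}

# Constant-duration protocol shortcut
steady_protocol <- function(atp, duration_s, phosphorylated = TRUE)
  protocol(atp, duration_s, phosphorylated = phosphorylated)

# Hand-built state path (for rendering tests with exact dwell control)
make_path <- function(states, dwells,
                      classes = data.frame(
                        name = unique(states),
                        fret_class = rep_len(c("low", "high"), length(unique(states))),
                        pore_conducting = rep_len(c(FALSE, TRUE), length(unique(states))),
                        stringsAsFactors = FALSE)) {
  entry <- cumsum(c(0, dwells[-length(dwells)]))
  structure(data.frame(state = states, entry_s = entry, dwell_s = dwells,
                       stringsAsFactors = FALSE),
            class = c("state_path", "data.frame"),
            hydrolysis_events = numeric(0), seed = 0L,
            variant = "custom", state_classes = classes)
}

# Quiet emission model: no noise, no blinking, no bleaching
clean_emission <- function(frame_ms = 100, ...)
  emission_model(frame_ms = frame_ms, intensity_noise_sd = 0,
                 blink_rate_per_s = 0, donor_bleach_mean_s = Inf, ...)
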