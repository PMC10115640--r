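# Rendering simulated paths into camera-sampled smFRET traces and
# low-pass-filtered single-channel currents.

# Running integral of a piecewise-constant function supported on the
# (sorted, possibly disjoint) intervals [entry, entry + dwell); zero
# outside them. Evaluation is clamped to each interval so times before
# the first segment integrate to zero.
.segment_integral <- function(entry, dwell, value) {
  cum <- c(0, cumsum(value * dwell))
  ends <- entry + dwell
  function(t) {
    i <- pmax(findInterval(t, entry), 1L)
    tc <- pmax(pmin(t, ends[i]), entry[i])
    cum[i] + (tc - entry[i]) * value[i]
  }
}

#' Render a simulated path into an smFRET trace
#'
#' Converts a `state_path` into a frame-sampled donor/acceptor intensity
#' trace. The true FRET efficiency of each frame is the dwell-time
#' weighted average of the state emission means inside the frame
#' (explicit camera time-averaging: sub-frame excursions are blurred to
#' intermediate apparent efficiencies). Acceptor intensity is
#' `total * E + noise`, donor `total * (1 - E) + noise`. A donor bleach
#' time is drawn from an exponential; from the bleach onward both
#' channels carry only noise (single-step bleaching). Donor blink
#' intervals (Poisson arrivals, exponential durations) transiently
#' silence both channels. Ground-truth per-frame class labels and
#' bleach/blink annotations are attached for downstream validation.
#'
#' Random draws, in fixed order (bleach time, blink arrivals and
#' durations, then per-channel noise), come from R's default RNG seeded
#' once per call, so identical inputs give bit-identical traces.
#'
#' @param path A `state_path` from [simulate_ssa()].
#' @param emission An [emission_model()].
#' @param seed Integer seed.
#' @param trace_id Identifier stored with the trace.
#' @return A `fret_trace`: data frame `frame`, `time_s`, `donor`,
#'   `acceptor`, with attributes `truth` (per-frame `fret_class`,
#'   `true_fret`, `visible_frac`), `bleach_s`, `blinks`, `frame_s`,
#'   `trace_id`.
#' @export
render_fret_trace <- function(path, emission, seed, trace_id = "trace1") {
  stopifnot(inherits(path, "state_path"), inherits(emission, "emission_model"))
  dt <- emission$frame_ms / 1000
  duration <- sum(path$dwell_s)
  n_frames <- floor(duration / dt + 1e-9)
  if (n_frames < 1L) stop("path shorter than one camera frame")
  cls_tab <- attr(path, "state_classes")
  if (is.null(cls_tab) || !"fret_class" %in% names(cls_tab))
    stop("path carries no state_classes table; simulate with simulate_ssa()")
  fclass <- cls_tab$fret_class[match(path$state, cls_tab$name)]
  means <- emission$fret_means[fclass]

  edges_t <- seq(0, n_frames) * dt
  f_int <- .segment_integral(path$entry_s, path$dwell_s, means)
  true_fret <- diff(f_int(edges_t)) / dt
  # per-frame class occupancy -> majority truth label
  occ <- sapply(names(emission$fret_means), function(cl) {
    v <- as.numeric(fclass == cl)
    diff(.segment_integral(path$entry_s, path$dwell_s, v)(edges_t))
  })
  truth_class <- colnames(occ)[max.col(occ, ties.method = "first")]

  set.seed(as.integer(seed))
  bleach_s <- if (is.finite(emission$donor_bleach_mean_s))
    stats::rexp(1L, 1 / emission$donor_bleach_mean_s) else Inf
  n_blinks <- stats::rpois(1L, emission$blink_rate_per_s * duration)
  blink_start <- sort(stats::runif(n_blinks, 0, duration))
  blink_dur <- stats::rexp(n_blinks, 1 / emission$blink_mean_dur_s)
  # fraction of each frame that is emitting: before bleach and not blinked
  vis <- pmin(pmax((bleach_s - edges_t[-length(edges_t)]) / dt, 0), 1)
  if (n_blinks > 0L) {
    dark1 <- rep(1, n_blinks)
    g <- .segment_integral(blink_start, blink_dur, dark1)
    blink_frac <- pmin(diff(g(edges_t)) / dt, 1)
    vis <- pmax(vis - blink_frac, 0)
  } else blink_frac <- numeric(n_frames)
  acceptor <- emission$total_intensity * true_fret * vis +
    stats::rnorm(n_frames, 0, emission$intensity_noise_sd)
  donor <- emission$total_intensity * (1 - true_fret) * vis +
    stats::rnorm(n_frames, 0, emission$intensity_noise_sd)

  out <- data.frame(frame = seq_len(n_frames),
                    time_s = (seq_len(n_frames) - 0.5) * dt,
                    donor = donor, acceptor = acceptor)
  truth <- data.frame(frame = out$frame, fret_class = truth_class,
                      true_fret = true_fret, visible_frac = vis,
                      blink_frac = blink_frac)
  structure(out, class = c("fret_trace", "data.frame"),
            truth = truth, bleach_s = bleach_s,
            blinks = data.frame(start_s = blink_start, dur_s = blink_dur),
            frame_s = dt, trace_id = trace_id, emission = emission,
            seed = as.integer(seed))
}

#' Render a simulated path into a single-channel current trace
#'
#' Conduction is a boxcar signal (`amplitude_pA` while the occupied state
#' conducts, 0 otherwise) sampled at `sample_hz`, plus Gaussian noise,
#' passed through a causal 4-pole low-pass Butterworth digital filter at
#' `filter_hz` - the digital stand-in for the analogue low-pass filtering
#' conventional in single-channel electrophysiology. Sub-resolution
#' flicker closures are therefore rendered as incompletely resolved
#' deflections, as in filtered recordings.
#'
#' @param path A `state_path` (must carry conducting flags).
#' @param amplitude_pA Open-channel current (> 0).
#' @param filter_hz Low-pass corner frequency.
#' @param noise_sd Pre-filter Gaussian noise sd (pA).
#' @param sample_hz Sampling rate; must be at least `10 * filter_hz`.
#' @param seed Integer seed.
#' @return A `current_trace` data frame `time_s`, `pA` with attributes
#'   `truth` (per-sample conducting flag), `open_amplitude_pA`,
#'   `filter_hz`, `noise_sd`.
#' @export
render_current_trace <- function(path, amplitude_pA = 0.5, filter_hz = 100,
                                 noise_sd = 0.15, sample_hz = 2000, seed = 1L) {
  stopifnot(inherits(path, "state_path"))
  if (amplitude_pA <= 0) stop("open amplitude must be positive")
  if (sample_hz < 10 * filter_hz)
    stop("sample_hz must be at least 10 * filter_hz")
  cls_tab <- attr(path, "state_classes")
  if (is.null(cls_tab) || !"pore_conducting" %in% names(cls_tab))
    stop("path carries no conducting flags")
  cond <- cls_tab$pore_conducting[match(path$state, cls_tab$name)]
  duration <- sum(path$dwell_s)
  t <- seq(0, duration - 1 / sample_hz, by = 1 / sample_hz)
  idx <- pmax(findInterval(t, path$entry_s), 1L)
  open <- cond[idx]
  set.seed(as.integer(seed))
  raw <- amplitude_pA * open + stats::rnorm(length(t), 0, noise_sd)
  bf <- signal::butter(4, filter_hz / (sample_hz / 2), type = "low")
  filt <- as.numeric(signal::filter(bf, raw))
  structure(data.frame(time_s = t, pA = filt),
            class = c("current_trace", "data.frame"),
            truth = data.frame(time_s = t, conducting = open),
            open_amplitude_pA = amplitude_pA, filter_hz = filter_hz,
            noise_sd = noise_sd, sample_hz = sample_hz,
            seed = as.integer(seed))
}

# Deterministic per-trace seed derivation from a master seed.
.derive_seed <- function(master, i) {
  as.integer((as.double(master) * 48271 + as.double(i) * 69621) %% 2147483563)
}

#' Generate an ensemble of synthetic smFRET traces
#'
#' Simulates `n_traces` independent gating trajectories under a common
#' protocol and renders each into an smFRET trace. Per-trace seeds are
#' derived deterministically from the master seed. Initial states are
#' drawn from the stationary distribution at the protocol's starting ATP
#' concentration when that chain is well defined, so steady-state
#' ensembles are unbiased from the first frame; otherwise traces start in
#' the apo separated state.
#'
#' @param graph A `state_graph`.
#' @param protocol A [protocol()].
#' @param n_traces Number of traces (>= 1).
#' @param emission An [emission_model()]; defaults to one matched to the
#'   protocol (ATP presence, phosphorylation) and the graph's variant.
#' @param seed Master integer seed.
#' @return A `trace_ensemble`: list with `traces`, `paths` and
#'   `metadata` (variant, protocol, n, seed, emission).
#' @export
generate_ensemble <- function(graph, protocol, n_traces, emission = NULL,
                              seed = 1L) {
  stopifnot(inherits(graph, "state_graph"), inherits(protocol, "protocol"),
            n_traces >= 1L)
  atp0 <- protocol$atp_schedule$atp_molar[1L]
  if (is.null(emission))
    emission <- emission_model(atp_bound = any(protocol$atp_schedule$atp_molar > 0),
                               phosphorylated = protocol$phosphorylated,
                               variant = graph$variant)
  g_eff <- .graph_for_protocol(graph, protocol)
  start_probs <- tryCatch(
    stationary_distribution(g_eff, max(atp0, 0))$occupancy,
    error = function(e) { p <- rep(0, nrow(graph$states)); p[1L] <- 1; p })
  set.seed(as.integer(seed))
  starts <- sample.int(nrow(graph$states), n_traces, replace = TRUE,
                       prob = start_probs)
  traces <- vector("list", n_traces)
  paths <- vector("list", n_traces)
  for (i in seq_len(n_traces)) {
    sp <- simulate_ssa(graph, protocol, seed = .derive_seed(seed, 2L * i),
                       start_state = starts[i])
    tr <- render_fret_trace(sp, emission, seed = .derive_seed(seed, 2L * i + 1L),
                            trace_id = sprintf("t%04d", i))
    paths[[i]] <- sp
    traces[[i]] <- tr
  }
  structure(list(traces = traces, paths = paths,
                 metadata = list(variant = graph$variant,
                                 phosphorylated = protocol$phosphorylated,
                                 n_traces = n_traces, seed = as.integer(seed),
                                 protocol = protocol, emission = emission)),
            class = "trace_ensemble")
}

#' @export
print.trace_ensemble <- function(x, ...) {
  md <- x$metadata
  cat(sprintf("<trace_ensemble> %d traces, variant %s (%s), seed %d\n",
              md$n_traces, md$variant,
              if (md$phosphorylated) "phosphorylated" else "dephosphorylated",
              md$seed))
  invisible(x)
}
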