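# High-level drivers for the standard validation computations.

#' Dwell-time asymmetry from stochastic simulation
#'
#' Runs seeded Gillespie simulations of a gating graph at fixed ATP,
#' extracts aggregated sojourns of the NBD-engaged (high/mid-FRET) class
#' and of conducting bursts (interruptions shorter than `bridge_s`
#' bridged, mirroring the filtering of single-channel records), and
#' returns the ratio of mean dwells pooled over all runs. Boundary
#' (censored) sojourns are excluded from the means.
#'
#' @param graph A `state_graph`.
#' @param atp ATP concentration (molar).
#' @param duration_s Duration of each simulation.
#' @param seeds Integer vector; one simulation per seed, pooled.
#' @param bridge_s Bridging time for conducting bursts (default 10 ms).
#' @return List with `ratio`, `mean_dimer_s`, `mean_burst_s`, `n_dimer`,
#'   `n_burst`.
#' @export
simulated_dwell_ratio <- function(graph, atp = 3e-3, duration_s = 2000,
                                  seeds = 1L, bridge_s = 0.01) {
  stopifnot(inherits(graph, "state_graph"))
  st <- graph$states
  open_map <- stats::setNames(ifelse(seq_len(nrow(st)) %in% graph$open_set,
                                     "open", "closed"), st$name)
  dimer_map <- stats::setNames(ifelse(seq_len(nrow(st)) %in% graph$dimer_set,
                                      "engaged", "separated"), st$name)
  dim_dw <- burst_dw <- numeric(0)
  for (s in seeds) {
    p <- simulate_ssa(graph, protocol(atp, duration_s), seed = s,
                      start_state = "DIM_closed")
    dd <- extract_dwells(p, aggregate_map = dimer_map)
    ob <- extract_dwells(p, aggregate_map = open_map, bridge_s = bridge_s,
                         bridge_class = "open")
    dim_dw <- c(dim_dw, dd$dwell_s[dd$class == "engaged" & !dd$censored])
    burst_dw <- c(burst_dw, ob$dwell_s[ob$class == "open" & !ob$censored])
  }
  if (!length(dim_dw) || !length(burst_dw))
    stop("simulation produced no uncensored sojourns; increase duration")
  list(ratio = mean(dim_dw) / mean(burst_dw),
       mean_dimer_s = mean(dim_dw), mean_burst_s = mean(burst_dw),
       n_dimer = length(dim_dw), n_burst = length(burst_dw))
}

#' Recover the central FRET of a condition from synthetic traces
#'
#' Runs the full synthetic round trip for one experimental condition:
#' simulate gating paths, render camera-sampled smFRET traces with the
#' condition's default emission parameters, apply quality control,
#' idealize with the standard two-state segmentation model, and pool the
#' re-estimated state means across accepted traces
#' (see [ensemble_state_means()]).
#'
#' @param variant Variant preset.
#' @param atp_molar ATP concentration.
#' @param phosphorylated Phosphorylation state.
#' @param n_traces Ensemble size.
#' @param duration_s Per-trace duration (s).
#' @param frame_ms Camera integration period.
#' @param seed Master seed.
#' @param reporter Which pooled mean to report: `"principal"` (highest
#'   qualifying state - the high-FRET state of dimerizing conditions),
#'   `"principal_low"` (lowest qualifying state) or `"modal"` (each
#'   trace's most-occupied state - the center of the predominant
#'   conformation).
#' @return List with `value` (the requested pooled mean), `means` (the
#'   full [ensemble_state_means()] output), `n_accepted`, `n_traces`.
#' @export
recovered_state_mean <- function(variant = "WT", atp_molar = 3e-3,
                                 phosphorylated = TRUE, n_traces = 300,
                                 duration_s = 60, frame_ms = 100, seed = 1L,
                                 reporter = c("principal", "principal_low",
                                              "modal")) {
  reporter <- match.arg(reporter)
  graph <- build_topology(variant, phosphorylated = phosphorylated)
  proto <- protocol(atp_molar, duration_s, phosphorylated = phosphorylated)
  emission <- emission_model(frame_ms = frame_ms, atp_bound = atp_molar > 0,
                             phosphorylated = phosphorylated,
                             variant = variant)
  ens <- generate_ensemble(graph, proto, n_traces, emission, seed = seed)
  ideal <- idealize_ensemble(ens)
  m <- ensemble_state_means(ideal$idealized)
  value <- switch(reporter, principal = m$principal_mean,
                  principal_low = m$principal_low_mean,
                  modal = m$modal_mean)
  list(value = value, means = m, n_accepted = length(ideal$idealized),
       n_traces = n_traces)
}
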