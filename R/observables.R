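# Deterministic model observables: the calibration and validation surface.

#' Deterministic channel observables of a gating model
#'
#' Computes, from exact CTMC quantities only (stationary solves, master
#' equation relaxations and mean-absorption dwell times - never stochastic
#' simulation), the panel of observables used to calibrate and validate
#' the model:
#'
#' * `po`, `pdim`, `turnover_per_s` - stationary values at saturating ATP;
#' * `coupling_ratio` - `po / pdim`;
#' * `dwell_ratio` - mean sojourn of the NBD-engaged class divided by the
#'   mean open-burst sojourn (flicker closures bridged, i.e. the burst is
#'   the aggregate of pre/post-hydrolytic open states and flickers);
#' * `tau_opening_s` - mono-exponential constant fitted to the rise of
#'   open occupancy after an instantaneous ATP jump from the
#'   phosphorylated apo state;
#' * `tau_sep_fast_s`, `tau_sep_slow_s` - bi-exponential constants fitted
#'   to the decay of NBD-engaged occupancy after complete ATP withdrawal
#'   from the saturating-ATP stationary state;
#' * `ec50_open_M`, `ec50_dim_M` - Hill midpoints (coefficient fixed to 1)
#'   of stationary `po` and `pdim` over a log-spaced ATP grid.
#'
#' Fit failures are flagged per observable in the `flags` field, never
#' silently defaulted.
#'
#' @param graph A `state_graph`.
#' @param rates Optional named rate overrides applied on top of the
#'   graph's rate set.
#' @param atp_sat Saturating ATP concentration (default 3 mM).
#' @param atp_grid ATP grid for the dose responses (molar); default 13
#'   log-spaced points from 1 uM to 3 mM.
#' @param activation_horizon_s,activation_grid_s Grid for the ATP-jump
#'   relaxation (defaults 6 s at 10 ms).
#' @param withdrawal_horizon_s,withdrawal_grid_s Grid for the
#'   ATP-withdrawal relaxation (defaults 90 s at 50 ms).
#' @return An `observable_set` list.
#' @export
observable_vector <- function(graph, rates = NULL, atp_sat = 3e-3,
                              atp_grid = 10^seq(log10(1e-6), log10(3e-3),
                                                length.out = 13),
                              activation_horizon_s = 6,
                              activation_grid_s = 0.01,
                              withdrawal_horizon_s = 90,
                              withdrawal_grid_s = 0.05) {
  stopifnot(inherits(graph, "state_graph"))
  if (!is.null(rates)) graph$rates[names(rates)] <- unlist(rates)
  flags <- character(0)
  note <- function(what) flags <<- c(flags, what)

  ss <- stationary_distribution(graph, atp_sat)
  Q <- generator_matrix(graph, atp_sat)
  nm <- graph$states$name
  burst_set <- which(nm %in% c("OPEN_pre", "FLICKER", "OPEN_post"))
  if (!length(burst_set)) burst_set <- graph$open_set
  dimer_dwell <- .mean_aggregate_dwell(Q, ss$occupancy, graph$dimer_set)
  burst_dwell <- .mean_aggregate_dwell(Q, ss$occupancy, burst_set)
  dwell_ratio <- dimer_dwell / burst_dwell

  # activation: ATP jump from the separated apo state
  p0 <- rep(0, nrow(graph$states))
  p0[1L] <- 1
  act <- occupancy_relaxation(graph, p0, atp_sat, activation_horizon_s,
                              activation_grid_s)
  tau_open <- tryCatch(
    fit_relaxation(act$time_s, act$po, n_components = 1L)$taus_s,
    error = function(e) { note("tau_opening"); NA_real_ })

  # withdrawal: ATP removed from the saturating stationary state
  wd <- occupancy_relaxation(graph, ss$occupancy, 0, withdrawal_horizon_s,
                             withdrawal_grid_s)
  taus_sep <- tryCatch({
    f <- fit_relaxation(wd$time_s, wd$pdim, n_components = 2L, offset = FALSE)
    if (!f$converged) note("tau_sep")
    f$taus_s
  }, error = function(e) { note("tau_sep"); c(NA_real_, NA_real_) })

  # dose responses
  po_c <- pdim_c <- numeric(length(atp_grid))
  for (i in seq_along(atp_grid)) {
    s <- stationary_distribution(graph, atp_grid[i])
    po_c[i] <- s$po
    pdim_c[i] <- s$pdim
  }
  ec50_open <- tryCatch(fit_hill(atp_grid, po_c)$ec50_M,
                        error = function(e) { note("ec50_open"); NA_real_ })
  ec50_dim <- tryCatch(fit_hill(atp_grid, pdim_c)$ec50_M,
                       error = function(e) { note("ec50_dim"); NA_real_ })

  structure(list(
    po = ss$po, pdim = ss$pdim,
    coupling_ratio = coupling_ratio(ss$po, ss$pdim),
    dwell_ratio = dwell_ratio,
    tau_opening_s = tau_open[1L],
    tau_sep_fast_s = taus_sep[1L], tau_sep_slow_s = taus_sep[2L],
    ec50_open_M = ec50_open, ec50_dim_M = ec50_dim,
    turnover_per_s = ss$turnover_per_s,
    dose = data.frame(atp_M = atp_grid, po = po_c, pdim = pdim_c),
    flags = flags), class = "observable_set")
}

#' @export
print.observable_set <- function(x, ...) {
  cat("<observable_set>\n")
  cat(sprintf("  Po = %.3f  Pdim = %.3f  coupling = %.3f  turnover = %.3f /s\n",
              x$po, x$pdim, x$coupling_ratio, x$turnover_per_s))
  cat(sprintf("  dwell ratio (dimerized/open burst) = %.1f\n", x$dwell_ratio))
  cat(sprintf("  tau_opening = %.0f ms; tau_sep = %.2f s / %.1f s\n",
              1000 * x$tau_opening_s, x$tau_sep_fast_s, x$tau_sep_slow_s))
  cat(sprintf("  EC50(open) = %.1f uM; EC50(dim) = %.1f uM\n",
              1e6 * x$ec50_open_M, 1e6 * x$ec50_dim_M))
  if (length(x$flags)) cat("  flagged fits:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Allosteric coupling ratio
#'
#' The open probability divided by the dimerization probability: the
#' fraction of NBD-engaged time during which the pore actually conducts.
#'
#' @param po Open probability (in `[0, 1]`).
#' @param pdim Dimerization probability (> 0).
#' @return `po / pdim`.
#' @export
coupling_ratio <- function(po, pdim) {
  stopifnot(is.numeric(po), is.numeric(pdim))
  if (any(pdim <= 0)) stop("coupling ratio undefined for pdim <= 0")
  po / pdim
}
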