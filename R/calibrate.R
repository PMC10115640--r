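# Constrained estimation of rate constants from channel observables.

#' Define a calibration target
#'
#' @param observable Name of a scalar field of [observable_vector()]
#'   output (e.g. `"po"`, `"tau_opening_s"`).
#' @param value Target value (point targets) or `NA` for window targets.
#' @param tolerance Relative tolerance used to scale the residual.
#' @param weight Positive weight.
#' @param window Optional `c(lo, hi)`; inside the window the residual is
#'   zero, outside it grows quadratically from the nearer edge.
#' @return A `calibration_target` list.
#' @export
calibration_target <- function(observable, value = NA_real_,
                               tolerance = 0.05, weight = 1,
                               window = NULL) {
  stopifnot(weight > 0, tolerance > 0)
  if (is.null(window) && is.na(value))
    stop("point targets need a value; window targets need a window")
  if (!is.null(window) && (length(window) != 2L || window[1L] >= window[2L]))
    stop("window must be c(lo, hi) with lo < hi")
  structure(list(observable = observable, value = value,
                 tolerance = tolerance, weight = weight, window = window),
            class = "calibration_target")
}

#' Default wild-type calibration targets
#'
#' The experimental observables the shipped wild-type rate set was
#' calibrated against, read from the package's target file
#' (`extdata/wt_targets.json`): stationary open and dimerization
#' probabilities at 3 mM ATP, the dimerized/open-burst dwell-time ratio,
#' activation and NBD-separation relaxation constants, ATP dose-response
#' midpoints, and a window on the ensemble hydrolysis rate (a window,
#' not a point, because the simple cycle model is known to overestimate
#' the measured ensemble turnover somewhat).
#'
#' @return List of [calibration_target()] objects.
#' @export
default_calibration_targets <- function() {
  f <- system.file("extdata", "wt_targets.json", package = "cftrgate")
  raw <- jsonlite::read_json(f, simplifyVector = FALSE)
  lapply(raw, function(x)
    calibration_target(x$observable,
                       value = if (is.null(x$value)) NA_real_ else x$value,
                       tolerance = x$tolerance,
                       weight = if (is.null(x$weight)) 1 else x$weight,
                       window = if (is.null(x$window)) NULL else unlist(x$window)))
}

.target_penalty <- function(obs, tg) {
  v <- obs[[tg$observable]]
  if (is.null(v) || !is.finite(v)) return(1e4 * tg$weight)
  if (!is.null(tg$window)) {
    lo <- tg$window[1L]; hi <- tg$window[2L]
    d <- if (v < lo) (lo - v) / (tg$tolerance * lo)
         else if (v > hi) (v - hi) / (tg$tolerance * hi)
         else 0
    return(tg$weight * d^2)
  }
  tg$weight * ((v - tg$value) / (tg$tolerance * tg$value))^2
}

#' Calibrate rate constants against observables
#'
#' Minimizes the weighted sum of squared scaled residuals
#' `sum(w * ((obs - target) / (tol * target))^2)` over log10-transformed
#' rate constants, by bounded multi-start local optimization (L-BFGS-B).
#' The objective uses only deterministic model quantities (see
#' [observable_vector()]), so it is noise-free; stochastic simulation is
#' reserved for validation. Restarts perturb the initial log-rates with a
#' seeded uniform jitter; ties between equal-objective restarts are broken
#' by the lowest restart index so the result is reproducible.
#'
#' @param targets List of [calibration_target()]s (order-invariant).
#' @param graph Base `state_graph` providing topology and fixed rates.
#' @param init Named numeric vector of starting rates; defaults to the
#'   graph's rates.
#' @param free Names of the rates to optimize (default: all rates that
#'   appear in the graph's edges).
#' @param bounds Named list mapping each free rate to `c(lo, hi)`;
#'   defaults to `[1e-3, 1e3]` 1/s for first-order rates and
#'   `[1e3, 1e8]` 1/M/s for second-order (ATP-proportional) rates,
#'   intersected with a +/- 2 decade box around the start.
#' @param restarts Number of starts (>= 1).
#' @param seed Integer seed controlling the restart jitter.
#' @param maxit L-BFGS-B iteration cap per start.
#' @param ... Passed to [observable_vector()] (e.g. coarser grids).
#' @return A `calibration_fit`: `rates` (full named vector),
#'   `objective`, `restart` (index of the winning start), `report` (per-
#'   target residuals with a `missed` flag), `observables`.
#' @export
calibrate_rates <- function(targets, graph, init = NULL, free = NULL,
                            bounds = NULL, restarts = 3L, seed = 1L,
                            maxit = 150L, ...) {
  stopifnot(inherits(graph, "state_graph"), restarts >= 1L)
  if (is.null(init)) init <- graph$rates
  if (is.null(free)) free <- intersect(names(init), unique(graph$edges$rate))
  if (!length(free)) stop("no free rates to calibrate")
  lo <- hi <- numeric(length(free))
  for (i in seq_along(free)) {
    b <- bounds[[free[i]]]
    if (is.null(b)) {
      b <- if (free[i] %in% graph$atp_dependent) c(1e3, 1e8) else c(1e-3, 1e3)
      b <- c(max(b[1L], init[[free[i]]] / 100), min(b[2L], init[[free[i]]] * 100))
    }
    if (b[1L] <= 0 || b[1L] >= b[2L]) stop("infeasible bounds for ", free[i])
    lo[i] <- log10(b[1L]); hi[i] <- log10(b[2L])
  }
  x0 <- log10(unlist(init[free]))
  x0 <- pmin(pmax(x0, lo), hi)

  objective <- function(x) {
    r <- init
    r[free] <- 10^x
    obs <- tryCatch(
      suppressWarnings(observable_vector(graph, rates = r, ...)),
      error = function(e) NULL)
    if (is.null(obs)) return(1e8)
    sum(vapply(targets, .target_penalty, numeric(1), obs = obs))
  }

  set.seed(as.integer(seed))
  starts <- vector("list", restarts)
  starts[[1L]] <- x0
  if (restarts > 1L)
    for (j in 2L:restarts)
      starts[[j]] <- pmin(pmax(x0 + stats::runif(length(x0), -0.5, 0.5), lo), hi)

  best <- NULL
  n_fail <- 0L
  for (j in seq_len(restarts)) {
    op <- tryCatch(
      stats::optim(starts[[j]], objective, method = "L-BFGS-B",
                   lower = lo, upper = hi,
                   control = list(maxit = maxit, factr = 1e9)),
      error = function(e) NULL)
    if (is.null(op)) { n_fail <- n_fail + 1L; next }
    if (is.null(best) || op$value < best$value - 1e-12)
      best <- list(value = op$value, par = op$par, restart = j)
  }
  if (is.null(best)) stop("all calibration restarts failed to converge")

  rates <- init
  rates[free] <- 10^best$par
  obs <- suppressWarnings(observable_vector(graph, rates = rates, ...))
  report <- do.call(rbind, lapply(targets, function(tg) {
    v <- obs[[tg$observable]]
    if (!is.null(tg$window)) {
      missed <- !is.finite(v) || v < tg$window[1L] * (1 - tg$tolerance) ||
        v > tg$window[2L] * (1 + tg$tolerance)
      data.frame(observable = tg$observable, target = NA_real_,
                 lo = tg$window[1L], hi = tg$window[2L], value = v,
                 rel_residual = NA_real_, missed = missed)
    } else {
      rel <- (v - tg$value) / tg$value
      data.frame(observable = tg$observable, target = tg$value,
                 lo = NA_real_, hi = NA_real_, value = v,
                 rel_residual = rel,
                 missed = !is.finite(rel) || abs(rel) > tg$tolerance)
    }
  }))
  structure(list(rates = rates, objective = best$value,
                 restart = best$restart, n_failed_restarts = n_fail,
                 report = report, observables = obs,
                 free = free, seed = as.integer(seed)),
            class = "calibration_fit")
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf("<calibration_fit> objective %.4g (restart %d)\n",
              x$objective, x$restart))
  print(x$report, row.names = FALSE)
  invisible(x)
}
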