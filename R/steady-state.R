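# Exact (linear-algebra) steady-state and relaxation computations.

#' Stationary occupancy of the gating chain
#'
#' Solves the global balance equations `t(Q) %*% pi = 0`, `sum(pi) = 1`
#' for the generator at a fixed ATP concentration and summarizes the
#' channel-level observables: open probability `po` (occupancy of
#' conducting states), dimerization probability `pdim` (occupancy of
#' NBD-engaged, high/mid-FRET states) and the hydrolysis turnover
#' `k3 * pi[OPEN_pre]` in events per second (zero for graphs without a
#' hydrolysis edge).
#'
#' @param graph A `state_graph`.
#' @param atp ATP concentration in molar; must be positive so the chain
#'   is irreducible (at zero ATP the apo separated state is absorbing).
#' @return A list with `occupancy` (named, non-negative, sums to one),
#'   `po`, `pdim` and `turnover_per_s`.
#' @export
stationary_distribution <- function(graph, atp) {
  stopifnot(inherits(graph, "state_graph"))
  if (!is.numeric(atp) || length(atp) != 1L || atp <= 0)
    stop("atp must be a single positive concentration (molar)")
  Q <- generator_matrix(graph, atp)
  n <- nrow(Q)
  A <- t(Q)
  A[n, ] <- 1
  b <- c(rep(0, n - 1L), 1)
  p <- tryCatch(solve(A, b), error = function(e)
    stop("singular generator: ", conditionMessage(e)))
  if (min(p) < -1e-8)
    stop("stationary solve produced significantly negative occupancy")
  p <- pmax(p, 0)
  p <- p / sum(p)
  names(p) <- graph$states$name
  turnover <- if ("k3" %in% graph$edges$rate && "OPEN_pre" %in% names(p))
    unname(graph$rates[["k3"]] * p[["OPEN_pre"]]) else 0
  list(occupancy = p,
       po = sum(p[graph$open_set]),
       pdim = sum(p[graph$dimer_set]),
       turnover_per_s = turnover)
}

#' Deterministic occupancy relaxation
#'
#' Integrates the master equation `dp/dt = t(Q) p` from an initial
#' occupancy vector at a fixed ATP concentration, by repeated application
#' of the matrix exponential propagator over a uniform grid. Exposes the
#' projections onto the conducting and NBD-engaged state sets for
#' downstream exponential fitting.
#'
#' @param graph A `state_graph`.
#' @param initial Initial occupancy vector (length = number of states,
#'   non-negative, summing to one within 1e-6). State names, if present,
#'   are checked against the graph.
#' @param atp ATP concentration in molar (>= 0; zero is allowed here, the
#'   relaxation towards the absorbing apo state is well defined).
#' @param horizon_s Final time (> 0).
#' @param grid_s Output grid spacing (> 0).
#' @return Data frame with columns `time_s`, `po`, `pdim`; the full
#'   occupancy matrix is attached as attribute `"occupancy"`.
#' @export
occupancy_relaxation <- function(graph, initial, atp, horizon_s, grid_s) {
  stopifnot(inherits(graph, "state_graph"), horizon_s > 0, grid_s > 0)
  n <- nrow(graph$states)
  if (length(initial) != n) stop("initial vector has wrong length")
  if (abs(sum(initial) - 1) > 1e-6) stop("initial occupancy must sum to 1")
  if (!is.null(names(initial)) &&
      !identical(names(initial), graph$states$name))
    initial <- initial[graph$states$name]
  Q <- generator_matrix(graph, atp)
  P <- as.matrix(Matrix::expm(t(Q) * grid_s))
  k <- ceiling(horizon_s / grid_s)
  occ <- matrix(0, k + 1L, n, dimnames = list(NULL, graph$states$name))
  p <- as.numeric(initial)
  occ[1L, ] <- p
  for (i in seq_len(k)) {
    p <- P %*% p
    occ[i + 1L, ] <- p
  }
  out <- data.frame(time_s = seq(0L, k) * grid_s,
                    po = rowSums(occ[, graph$open_set, drop = FALSE]),
                    pdim = rowSums(occ[, graph$dimer_set, drop = FALSE]))
  attr(out, "occupancy") <- occ
  out
}

# Mean sojourn time of an aggregate class entered at stationarity.
#
# Entry weights are the stationary probability fluxes from outside the
# class into each member state; the mean absorption time to leave the
# class follows from the sub-generator restricted to the class.
.mean_aggregate_dwell <- function(Q, pi, class_idx) {
  A <- class_idx
  B <- setdiff(seq_len(nrow(Q)), A)
  if (!length(B)) return(Inf)
  w <- colSums(Q[B, A, drop = FALSE] * pi[B])
  if (sum(w) <= 0) return(NA_real_)
  w <- w / sum(w)
  tau <- solve(-Q[A, A, drop = FALSE], rep(1, length(A)))
  sum(w * tau)
}
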