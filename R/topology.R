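# Gating-cycle topology: states, rate presets and graph construction.

#' Canonical state names of the CFTR gating cycle
#'
#' The nine states of the package's canonical gating-cycle topology, in
#' their fixed internal order: NBD-separated apo channel (`SEP_apo`),
#' NBD-separated ATP-bound channel (`SEP_atp`), pre-open NBD dimer
#' (`DIM_closed`), pre-hydrolytic open channel (`OPEN_pre`), flicker-closed
#' substate sampled from the open burst (`FLICKER`), post-hydrolytic open
#' channel (`OPEN_post`), non-conductive ADP-bound dimer (`DIM_ADP`),
#' nucleotide-exchange intermediate with the NBD interface still engaged
#' (`INT_dimer`) and its partially separated counterpart (`INT_sep`).
#'
#' @return Character vector of length nine.
#' @export
gating_states <- function() {
  c("SEP_apo", "SEP_atp", "DIM_closed", "OPEN_pre", "FLICKER",
    "OPEN_post", "DIM_ADP", "INT_dimer", "INT_sep")
}

#' Rate-constant names of the gating cycle
#'
#' @return Character vector with the thirteen rate-constant names. `k_bind`
#'   and `k6` are second-order ATP association constants (M^-1 s^-1); all
#'   others are first-order (s^-1).
#' @export
rate_names <- function() {
  c("k_bind", "k_unbind", "k1", "k2", "k3", "k_flick_on", "k_flick_off",
    "k4", "k5", "k6", "k7_fwd", "k7_rev", "k8")
}

# Rates whose propensity is rate * [ATP]
.atp_dependent_rates <- c("k_bind", "k6")

# Directed edges of the canonical topology (13 transitions).
.cycle_edges <- function() {
  data.frame(
    from = c("SEP_apo", "SEP_atp", "SEP_atp", "DIM_closed", "OPEN_pre",
             "FLICKER", "OPEN_pre", "OPEN_post", "DIM_ADP", "INT_dimer",
             "INT_sep", "INT_dimer", "INT_sep"),
    to   = c("SEP_atp", "SEP_apo", "DIM_closed", "OPEN_pre", "FLICKER",
             "OPEN_pre", "OPEN_post", "DIM_ADP", "INT_dimer", "INT_sep",
             "INT_dimer", "DIM_closed", "SEP_atp"),
    rate = c("k_bind", "k_unbind", "k1", "k2", "k_flick_on", "k_flick_off",
             "k3", "k4", "k5", "k7_fwd", "k7_rev", "k6", "k8"),
    stringsAsFactors = FALSE)
}

#' Wild-type and variant rate constants
#'
#' Returns the package's calibrated wild-type rate set, optionally modified
#' by a variant preset. The wild-type values are outputs of
#' [calibrate_rates()] against steady-state and pre-steady-state channel
#' observables (open and dimerization probabilities at saturating ATP,
#' dwell-time asymmetry, activation and separation relaxation constants,
#' ATP dose-response midpoints and the ensemble hydrolysis rate); they are
#' not independently measured microscopic constants. Variant presets
#' override a small, documented subset of rates to reproduce each variant's
#' qualitative phenotype:
#'
#' * `E1371Q` - catalytic-base substitution; hydrolysis (`k3`) is set to a
#'   vanishingly small value so simulated paths contain essentially no
#'   hydrolysis events and NBD separation is dramatically slowed.
#' * `G551D` - consensus-site substitution; opening (`k2`) is nearly
#'   abolished, so hydrolysis flux collapses and the channel dwells in a
#'   non-conductive, intermediate NBD conformation.
#' * `L927P` - transmembrane-hinge substitution; opening is strongly
#'   suppressed and open bursts are cut roughly fifteen-fold short.
#' * `W401A` - degenerate-site substitution; the partially separated
#'   exchange intermediate resolves directly to full separation.
#' * `Y1219A` - consensus-site binding substitution; opening and
#'   hydrolysis are nearly abolished and commitment to the full dimer is
#'   weakened.
#'
#' @param variant One of `"WT"`, `"E1371Q"`, `"W401A"`, `"Y1219A"`,
#'   `"G551D"`, `"L927P"`.
#' @return Named numeric vector over [rate_names()].
#' @export
cftr_rates <- function(variant = "WT") {
  variant <- match.arg(variant, .known_variants)
  r <- .wt_calibrated_rates
  ov <- .variant_overrides[[variant]]
  if (!is.null(ov)) r[names(ov)] <- ov
  r
}

.known_variants <- c("WT", "E1371Q", "W401A", "Y1219A", "G551D", "L927P")

# Calibration output (see calibrate_rates and the package vignette).
.wt_calibrated_rates <- c(
  k_bind      = 3.411849e+04,
  k_unbind    = 4.252245e+00,
  k1          = 6.353043e+00,
  k2          = 5.314029e-01,
  k3          = 1.513806e+00,
  k_flick_on  = 1.000000e+01,
  k_flick_off = 7.000000e+02,
  k4          = 9.985696e+02,
  k5          = 3.443808e+02,
  k6          = 1.533140e+06,
  k7_fwd      = 9.425066e+02,
  k7_rev      = 2.678124e-01,
  k8          = 1.640158e-01)

.variant_overrides <- list(
  WT     = NULL,
  E1371Q = c(k3 = 1e-6),
  G551D  = c(k2 = 0.02, k3 = 5),
  L927P  = c(k2 = 0.05, k3 = 22.7),
  W401A  = c(k8 = 10, k7_rev = 0.01, k1 = 13),
  Y1219A = c(k2 = 0.02, k3 = 0.02, k1 = 5))

# Variants whose non-conducting dimer-class states only reach an
# intermediate degree of NBD approach (mid-FRET emission).
.intermediate_variants <- c("G551D", "L927P")

.state_table <- function(variant) {
  name <- gating_states()
  nbd <- c("separated", "separated", "dimerized", "dimerized", "dimerized",
           "dimerized", "dimerized", "intermediate", "separated")
  if (variant %in% .intermediate_variants) {
    # Partial NBD approach: the closed-dimer states sit at an intermediate
    # separation; the (rare) conducting states retain the fully dimerized
    # conformation.
    nbd[match(c("DIM_closed", "DIM_ADP"), name)] <- "intermediate"
  }
  conducting <- name %in% c("OPEN_pre", "OPEN_post")
  consensus <- c("empty", "ATP", "ATP", "ATP", "ATP",
                 "ADP_Pi", "ADP", "empty", "empty")
  degenerate <- c("empty", "ATP", "ATP", "ATP", "ATP",
                  "ATP", "ATP", "ATP", "ATP")
  fret <- c(separated = "low", dimerized = "high",
            intermediate = if (variant %in% .intermediate_variants) "mid" else "high")[nbd]
  data.frame(name = name, nbd_class = nbd, pore_conducting = conducting,
             consensus_occupancy = consensus, degenerate_occupancy = degenerate,
             fret_class = unname(fret), stringsAsFactors = FALSE)
}

#' Construct a gating-cycle state graph
#'
#' Builds the nine-state, thirteen-transition continuous-time Markov graph
#' of the gating cycle for a given variant, optionally overriding
#' individual rate constants. Openings occur only from NBD-dimerized
#' states, so the allosteric coupling ratio (open probability divided by
#' dimerization probability) is structurally bounded by one. In
#' dephosphorylated channels the regulatory domain blocks NBD
#' dimerization; pass `phosphorylated = FALSE` to force the dimerization
#' rate `k1` to zero.
#'
#' @param variant Variant preset name; see [cftr_rates()].
#' @param overrides Named list or vector of rate overrides (a subset of
#'   [rate_names()]); values must be non-negative.
#' @param phosphorylated Logical; dephosphorylated graphs have `k1 = 0`.
#' @return A `state_graph` object: states table, rate set, edge list and
#'   the conducting (`open_set`) and NBD-engaged (`dimer_set`) index sets.
#' @examples
#' g <- build_topology("WT")
#' nrow(g$edges)   # 13 directed transitions
#' @export
build_topology <- function(variant = "WT", overrides = NULL,
                           phosphorylated = TRUE) {
  variant <- match.arg(variant, .known_variants)
  rates <- cftr_rates(variant)
  if (length(overrides)) {
    overrides <- unlist(overrides)
    bad <- setdiff(names(overrides), rate_names())
    if (length(bad))
      stop("unknown rate name(s): ", paste(bad, collapse = ", "))
    if (any(!is.finite(overrides)) || any(overrides < 0))
      stop("rate overrides must be finite and non-negative")
    rates[names(overrides)] <- overrides
  }
  if (!phosphorylated) rates[["k1"]] <- 0
  st <- .state_table(variant)
  state_graph(st, .cycle_edges(), rates,
              open_set = which(st$pore_conducting),
              dimer_set = which(st$nbd_class %in% c("dimerized", "intermediate")),
              atp_dependent = .atp_dependent_rates,
              variant = variant, phosphorylated = phosphorylated)
}

#' Low-level state-graph constructor
#'
#' Assembles an arbitrary labelled continuous-time Markov graph. Used
#' internally by [build_topology()] and directly for small reference
#' graphs (e.g. two-state toys in unit tests).
#'
#' @param states Data frame with at least a `name` column; optional
#'   columns `pore_conducting` and `fret_class` are used by the rendering
#'   layer.
#' @param edges Data frame with columns `from`, `to`, `rate` (rate name).
#' @param rates Named numeric vector of non-negative rate constants
#'   covering every name in `edges$rate`.
#' @param open_set,dimer_set Integer state indices of conducting and
#'   NBD-engaged (high/mid-FRET) states.
#' @param atp_dependent Names of rates scaled by the ATP concentration.
#' @param variant,phosphorylated Metadata carried along for provenance.
#' @return A `state_graph` object.
#' @export
state_graph <- function(states, edges, rates, open_set = integer(),
                        dimer_set = integer(), atp_dependent = character(),
                        variant = "custom", phosphorylated = TRUE) {
  stopifnot(is.data.frame(states), "name" %in% names(states),
            is.data.frame(edges),
            all(c("from", "to", "rate") %in% names(edges)))
  if (anyDuplicated(states$name)) stop("duplicate state names")
  if (!all(edges$from %in% states$name) || !all(edges$to %in% states$name))
    stop("edge endpoints must be state names")
  if (!all(edges$rate %in% names(rates)))
    stop("every edge rate must be present in `rates`")
  if (any(rates < 0) || any(!is.finite(rates)))
    stop("rates must be finite and non-negative")
  g <- structure(list(
    variant = variant, phosphorylated = phosphorylated,
    states = states, rates = rates, edges = edges,
    open_set = as.integer(open_set), dimer_set = as.integer(dimer_set),
    atp_dependent = atp_dependent), class = "state_graph")
  g
}

#' @export
print.state_graph <- function(x, ...) {
  cat(sprintf("<state_graph> %s (%s), %d states, %d transitions\n",
              x$variant,
              if (x$phosphorylated) "phosphorylated" else "dephosphorylated",
              nrow(x$states), nrow(x$edges)))
  cat("  conducting:", paste(x$states$name[x$open_set], collapse = ", "), "\n")
  cat("  NBD-engaged:", paste(x$states$name[x$dimer_set], collapse = ", "), "\n")
  invisible(x)
}

#' Generator matrix at a given ATP concentration
#'
#' @param graph A `state_graph`.
#' @param atp ATP concentration (molar, >= 0). Second-order rates are
#'   multiplied by `atp`.
#' @return Square rate matrix with zero row sums (off-diagonal entries are
#'   transition propensities, the diagonal the negative total outflow).
#' @export
generator_matrix <- function(graph, atp) {
  stopifnot(inherits(graph, "state_graph"), is.numeric(atp), atp >= 0)
  nm <- graph$states$name
  n <- length(nm)
  Q <- matrix(0, n, n, dimnames = list(nm, nm))
  e <- graph$edges
  r <- graph$rates[e$rate]
  scale <- ifelse(e$rate %in% graph$atp_dependent, atp, 1)
  for (i in seq_len(nrow(e)))
    Q[e$from[i], e$to[i]] <- Q[e$from[i], e$to[i]] + r[i] * scale[i]
  diag(Q) <- diag(Q) - rowSums(Q)
  Q
}

#' ATP/condition protocol
#'
#' A piecewise-constant ATP schedule plus the phosphorylation state of the
#' channel. ADP is not modelled and is fixed at zero.
#'
#' @param atp Either a single molar concentration (held for the whole
#'   protocol) or a data frame with columns `start_s`, `atp_molar` whose
#'   start times strictly increase from 0.
#' @param duration_s Total duration in seconds (> 0).
#' @param phosphorylated Logical. Dephosphorylated channels cannot
#'   dimerize (`k1` forced to 0 during simulation).
#' @param temperature_C Informational only.
#' @return A `protocol` object.
#' @export
protocol <- function(atp, duration_s, phosphorylated = TRUE,
                     temperature_C = 22) {
  if (is.numeric(atp) && length(atp) == 1L)
    atp <- data.frame(start_s = 0, atp_molar = atp)
  stopifnot(is.data.frame(atp),
            all(c("start_s", "atp_molar") %in% names(atp)))
  if (nrow(atp) == 0L) stop("empty ATP schedule")
  if (atp$start_s[1] != 0) stop("ATP schedule must start at time 0")
  if (any(diff(atp$start_s) <= 0)) stop("schedule start times must strictly increase")
  if (any(atp$atp_molar < 0)) stop("ATP concentrations must be >= 0")
  if (!is.numeric(duration_s) || duration_s <= 0) stop("duration_s must be > 0")
  structure(list(atp_schedule = atp, duration_s = duration_s,
                 phosphorylated = phosphorylated, adp_molar = 0,
                 temperature_C = temperature_C),
            class = "protocol")
}

# ATP concentration of a protocol at time t (vectorized)
.protocol_atp_at <- function(protocol, t) {
  idx <- findInterval(t, protocol$atp_schedule$start_s)
  protocol$atp_schedule$atp_molar[pmax(idx, 1L)]
}

# Apply the phosphorylation switch of a protocol to a graph
.graph_for_protocol <- function(graph, protocol) {
  if (!protocol$phosphorylated) graph$rates[["k1"]] <- 0
  graph
}
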