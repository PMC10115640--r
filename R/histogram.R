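# Population FRET histograms across experimental groups.

#' Population FRET histogram with per-group errors
#'
#' Builds normalized FRET-efficiency histograms per experimental group
#' and averages them, reporting the mean and standard error of each bin
#' across groups - the conventional presentation for population smFRET
#' distributions. When idealized traces are supplied, the high-FRET
#' occupancy (fraction of assigned frames in the upper state) is
#' summarized as well.
#'
#' @param x A list of `idealized_trace` objects, a list of
#'   [compute_fret()] outputs, or a `trace_ensemble` (FRET computed on
#'   the fly).
#' @param bins Bin edges on the efficiency axis.
#' @param groups Integer or factor of length `length(x)` assigning each
#'   trace to an experimental group; default: a single group.
#' @return An `ensemble_histogram` list: `bin_mid`, `density_mean`,
#'   `density_se`, `n_groups`, and (when available) `high_fret_occupancy`
#'   with its per-group values.
#' @export
ensemble_histogram <- function(x, bins = seq(0, 1, by = 0.02),
                               groups = NULL) {
  if (inherits(x, "trace_ensemble"))
    x <- lapply(x$traces, compute_fret)
  stopifnot(is.list(x), length(x) >= 1L)
  if (is.null(groups)) groups <- rep(1L, length(x))
  if (length(groups) != length(x) || anyNA(groups))
    stop("groups must assign every trace to a group")
  gl <- split(seq_along(x), groups)
  if (any(vapply(gl, length, integer(1)) == 0L)) stop("empty group")

  dens <- matrix(NA_real_, length(gl), length(bins) - 1L)
  occ <- rep(NA_real_, length(gl))
  for (g in seq_along(gl)) {
    vals <- unlist(lapply(x[gl[[g]]], function(tr) {
      v <- tr$fret
      v[!is.na(v)]
    }))
    if (!length(vals)) stop("group ", names(gl)[g], " has no usable frames")
    h <- graphics::hist(vals[vals >= bins[1L] & vals <= bins[length(bins)]],
                        breaks = bins, plot = FALSE)
    dens[g, ] <- h$density
    states <- unlist(lapply(x[gl[[g]]], function(tr)
      if ("state" %in% names(tr)) tr$state else NULL))
    if (length(states))
      occ[g] <- mean(states == max(states, na.rm = TRUE), na.rm = TRUE)
  }
  se <- if (nrow(dens) > 1L) apply(dens, 2L, stats::sd) / sqrt(nrow(dens))
        else rep(NA_real_, ncol(dens))
  out <- list(bin_mid = (bins[-1L] + bins[-length(bins)]) / 2,
              density_mean = colMeans(dens), density_se = se,
              n_groups = length(gl))
  if (any(is.finite(occ))) {
    out$high_fret_occupancy <- mean(occ, na.rm = TRUE)
    out$high_fret_occupancy_by_group <- occ
  }
  structure(out, class = "ensemble_histogram")
}

#' @export
print.ensemble_histogram <- function(x, ...) {
  cat(sprintf("<ensemble_histogram> %d groups, %d bins", x$n_groups,
              length(x$bin_mid)))
  if (!is.null(x$high_fret_occupancy))
    cat(sprintf(", high-FRET occupancy %.3f", x$high_fret_occupancy))
  cat("\n")
  invisible(x)
}
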