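# Segmental k-means idealization of FRET trajectories.

#' Two-state segmentation model
#'
#' The segmental k-means model used for idealization: two non-zero-FRET
#' states with Gaussian emissions (defaults 0.25 +/- 0.1 and
#' 0.48 +/- 0.1). State means may be re-estimated from the assigned
#' frames; the emission standard deviations stay fixed. The segmentation
#' prior is a single uniform log-penalty per state switch. States whose
#' re-estimated means approach each other within `merge_threshold` are
#' merged after convergence, since two Gaussians closer than one model
#' standard deviation are not separable at the single-trace level.
#'
#' @param means Initial state means, strictly increasing.
#' @param sds Emission standard deviations (> 0), one per state.
#' @param re_estimate Re-estimate means from assignments (default TRUE).
#' @param switch_penalty Log-penalty (nats) per state switch in the
#'   most-likely-path segmentation.
#' @param merge_threshold Minimum separation of re-estimated means below
#'   which states are merged (default: the smaller model sd).
#' @param max_iter Iteration cap for the assign/re-estimate loop.
#' @return An `skm_model` list.
#' @export
skm_model <- function(means = c(0.25, 0.48), sds = c(0.1, 0.1),
                      re_estimate = TRUE, switch_penalty = 3,
                      merge_threshold = NULL, max_iter = 20L) {
  stopifnot(length(means) == length(sds), length(means) >= 2L,
            all(diff(means) > 0), all(sds > 0), switch_penalty >= 0)
  if (is.null(merge_threshold)) merge_threshold <- min(sds)
  structure(list(means = means, sds = sds, re_estimate = re_estimate,
                 switch_penalty = switch_penalty,
                 merge_threshold = merge_threshold,
                 max_iter = as.integer(max_iter)),
            class = "skm_model")
}

# Most-likely state path under Gaussian emissions with a uniform switch
# penalty (Viterbi on a chain whose transition cost is 0 to stay and
# `penalty` to switch).
.viterbi_segment <- function(x, means, sds, penalty) {
  n <- length(x)
  S <- length(means)
  em <- vapply(seq_len(S), function(s)
    stats::dnorm(x, means[s], sds[s], log = TRUE), numeric(n))
  em <- matrix(em, nrow = n)
  back <- matrix(0L, n, S)
  v <- em[1L, ]
  for (t in 2L:n) {
    # cost of arriving in state s: stay (v[s]) vs best switch (max v - penalty)
    stay <- v
    jmax <- which.max(v)
    sw <- v[jmax] - penalty
    for (s in seq_len(S)) {
      if (stay[s] >= sw) back[t, s] <- s
      else back[t, s] <- if (jmax != s) jmax else which.max(v[-s]) + (which.max(v[-s]) >= s)
    }
    v <- em[t, ] + pmax(stay, sw)
  }
  path <- integer(n)
  path[n] <- which.max(v)
  if (n > 1L) for (t in n:2L) path[t - 1L] <- back[t, path[t]]
  list(path = path, loglik = max(v))
}

#' Segmental k-means idealization
#'
#' Assigns each usable frame of a FRET series to a discrete state by
#' iterating (a) the most-likely state path under Gaussian emissions with
#' a uniform switch penalty and (b) re-estimation of the state means from
#' the assigned frames. Iteration stops when the assignment no longer
#' changes or after `max_iter` passes (flagged, last iterate returned).
#' Dark frames (blinks, post-bleach) are excluded from both segmentation
#' and re-estimation. The path log-likelihood is non-decreasing over
#' iterations. States left with fewer than two assigned frames keep
#' their initial means; states whose means converge within the model's
#' merge threshold are merged.
#'
#' @param fret Output of [compute_fret()] (columns `fret`, `dark`), or a
#'   bare numeric vector of efficiencies (`NA` = dark).
#' @param model An [skm_model()].
#' @param last_frame Optional last analyzable frame (e.g. the detected
#'   bleach frame from QC); later frames are treated as dark.
#' @return An `idealized_trace`: data frame `frame`, `fret`, `state`
#'   (integer, `NA` on dark frames), `label` (`"low"`/`"high"`/`"dark"`),
#'   with attributes `means` (re-estimated), `occupancy` (frame fraction
#'   per state), `loglik`, `n_iter`, `converged`, `merged`, `frame_s`,
#'   `trace_id`.
#' @export
skm_idealize <- function(fret, model = skm_model(), last_frame = NULL) {
  if (is.numeric(fret)) fret <- data.frame(frame = seq_along(fret),
                                           fret = fret, dark = is.na(fret))
  stopifnot(is.data.frame(fret), all(c("fret", "dark") %in% names(fret)),
            inherits(model, "skm_model"))
  n <- nrow(fret)
  dark <- fret$dark | is.na(fret$fret)
  if (!is.null(last_frame) && last_frame < n)
    dark[(last_frame + 1L):n] <- TRUE
  use <- which(!dark)
  if (length(use) < 2L) stop("fewer than two usable (non-dark) frames")
  x <- fret$fret[use]

  means <- model$means
  S <- length(means)
  assign_prev <- NULL
  loglik <- -Inf
  ll_trace <- numeric(0)
  converged <- FALSE
  n_iter <- 0L
  repeat {
    n_iter <- n_iter + 1L
    vt <- .viterbi_segment(x, means, model$sds, model$switch_penalty)
    ll_trace <- c(ll_trace, vt$loglik)
    if (identical(vt$path, assign_prev)) { converged <- TRUE; break }
    assign_prev <- vt$path
    loglik <- vt$loglik
    if (model$re_estimate) {
      for (s in seq_len(S)) {
        xs <- x[vt$path == s]
        if (length(xs) >= 2L) means[s] <- mean(xs)
      }
      # keep the state order stable
      o <- order(means)
      means <- means[o]
      assign_prev <- match(assign_prev, o)
    }
    if (n_iter >= model$max_iter) break
  }
  if (!converged)
    warning("segmental k-means did not converge; returning last iterate")
  path <- assign_prev

  merged <- FALSE
  if (S == 2L && diff(means) < model$merge_threshold) {
    merged <- TRUE
    keep <- if (sum(path == 1L) >= sum(path == 2L)) 1L else 2L
    means[keep] <- mean(x)
    path[] <- keep
  }

  occupancy <- vapply(seq_len(S), function(s) mean(path == s), numeric(1))
  state <- rep(NA_integer_, n)
  state[use] <- path
  label_lu <- if (S == 2L) c("low", "high") else paste0("s", seq_len(S))
  label <- ifelse(is.na(state), "dark", label_lu[state])
  out <- data.frame(frame = fret$frame, fret = fret$fret,
                    state = state, label = label,
                    stringsAsFactors = FALSE)
  structure(out, class = c("idealized_trace", "data.frame"),
            means = means, occupancy = occupancy, loglik = loglik,
            loglik_trace = ll_trace,
            n_iter = n_iter, converged = converged, merged = merged,
            model = model,
            frame_s = attr(fret, "frame_s"),
            trace_id = attr(fret, "trace_id"))
}

#' Idealize an ensemble of traces
#'
#' Convenience wrapper: computes FRET, applies QC, and idealizes every
#' accepted trace up to its detected bleach frame.
#'
#' @param ensemble A `trace_ensemble` or list of `fret_trace`s.
#' @param model An [skm_model()].
#' @param criteria [qc_criteria()] for selection.
#' @return List with `idealized` (list of `idealized_trace`), `qc` (the
#'   [qc_select()] result) and `model`.
#' @export
idealize_ensemble <- function(ensemble, model = skm_model(),
                              criteria = qc_criteria()) {
  traces <- if (inherits(ensemble, "trace_ensemble")) ensemble$traces else ensemble
  qc <- qc_select(traces, criteria)
  idx <- which(qc$accepted)
  ideal <- vector("list", length(idx))
  for (j in seq_along(idx)) {
    i <- idx[j]
    ef <- compute_fret(traces[[i]])
    ideal[[j]] <- skm_idealize(ef, model,
                               last_frame = qc$report$bleach_frame[i])
  }
  list(idealized = ideal, qc = qc, model = model)
}

#' Ensemble summary of re-estimated state means
#'
#' Pools per-trace re-estimated state means across an idealized
#' ensemble. For each trace, states occupying at least `min_occupancy`
#' of the usable frames qualify; the trace's "principal" state is the
#' qualifying state with the highest mean (for a one-state trace this is
#' simply its occupied state). Ensemble values are frame-weighted means
#' across traces.
#'
#' @param idealized List of `idealized_trace` objects (e.g. from
#'   [idealize_ensemble()]).
#' @param min_occupancy Minimum frame fraction for a state to qualify.
#' @return List with `by_state` (data frame: state, pooled mean, total
#'   frames, traces contributing), `principal_mean` (frame-weighted mean
#'   of each trace's highest qualifying state), `principal_low_mean`
#'   (same for the lowest qualifying state) and `modal_mean` (same for
#'   each trace's most-occupied state - the central efficiency of the
#'   predominant conformation).
#' @export
ensemble_state_means <- function(idealized, min_occupancy = 0.1) {
  stopifnot(is.list(idealized), length(idealized) >= 1L)
  rows <- list()
  prin_hi <- prin_lo <- modal <- matrix(numeric(0), ncol = 2L)
  for (tr in idealized) {
    mu <- attr(tr, "means")
    occ <- attr(tr, "occupancy")
    nuse <- sum(!is.na(tr$state))
    qual <- which(occ >= min_occupancy)
    if (!length(qual)) next
    for (s in qual)
      rows[[length(rows) + 1L]] <- data.frame(state = s, mean = mu[s],
                                              frames = occ[s] * nuse)
    hi <- qual[which.max(mu[qual])]
    lo <- qual[which.min(mu[qual])]
    md <- qual[which.max(occ[qual])]
    prin_hi <- rbind(prin_hi, c(mu[hi], occ[hi] * nuse))
    prin_lo <- rbind(prin_lo, c(mu[lo], occ[lo] * nuse))
    modal <- rbind(modal, c(mu[md], occ[md] * nuse))
  }
  if (!length(rows)) stop("no qualifying states in the ensemble")
  tab <- do.call(rbind, rows)
  by_state <- do.call(rbind, lapply(split(tab, tab$state), function(d)
    data.frame(state = d$state[1L],
               mean = sum(d$mean * d$frames) / sum(d$frames),
               frames = sum(d$frames), traces = nrow(d))))
  wmean <- function(m) sum(m[, 1L] * m[, 2L]) / sum(m[, 2L])
  list(by_state = by_state,
       principal_mean = wmean(prin_hi),
       principal_low_mean = wmean(prin_lo),
       modal_mean = wmean(modal))
}
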