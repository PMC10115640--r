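# Trace selection: the deterministic quality-control chain applied
# before idealization.

#' Quality-control criteria for smFRET traces
#'
#' The selection thresholds applied by [qc_select()], mirroring standard
#' practice for camera-based single-molecule imaging: single-step donor
#' photobleaching, signal-to-noise ratio above 8, fewer than four donor
#' blinking events, FRET efficiency above baseline for at least 50
#' frames, and exclusion of traces dwelling above 0.8 efficiency
#' (a nucleotide-insensitive subpopulation attributed to denatured
#' molecules). The baseline value and the tolerated fraction of
#' above-maximum frames are package defaults, serialized with every QC
#' report.
#'
#' @param min_snr Minimum signal-to-noise ratio (mean total intensity
#'   before bleach over its standard deviation).
#' @param max_blinks Maximum tolerated donor blink count ("fewer than 4"
#'   means a default of 3).
#' @param min_frames_above_baseline Minimum number of analyzable frames
#'   with FRET above `baseline`.
#' @param require_single_step_bleach Reject traces with multi-step or
#'   absent photobleaching.
#' @param max_fret Efficiency ceiling; traces spending more than
#'   `max_fret_frac` of analyzable frames above it are excluded.
#' @param max_fret_frac Tolerated fraction of frames above `max_fret`
#'   (guards against rejecting a clean trace for isolated noise
#'   excursions).
#' @param baseline FRET efficiency regarded as background.
#' @param min_bleach_depletion Fractional intensity drop a candidate
#'   bleach step must reach.
#' @return A `qc_criteria` list.
#' @export
qc_criteria <- function(min_snr = 8, max_blinks = 3,
                        min_frames_above_baseline = 50,
                        require_single_step_bleach = TRUE,
                        max_fret = 0.8, max_fret_frac = 0.02,
                        baseline = 0.1, min_bleach_depletion = 0.8) {
  stopifnot(min_snr > 0, max_blinks >= 0, min_frames_above_baseline > 0,
            max_fret > 0, baseline > 0,
            min_bleach_depletion > 0, min_bleach_depletion < 1)
  structure(as.list(environment()), class = "qc_criteria")
}

# Change-point on total intensity: index k maximizing the between-segment
# SSE reduction for a one-step mean shift; returns NULL if no admissible
# downward step reaches the required depletion.
.detect_step <- function(total, min_depletion, min_seg = 3L) {
  n <- length(total)
  if (n < 2L * min_seg) return(NULL)
  cs <- cumsum(total); cs2 <- cumsum(total^2)
  k <- seq(min_seg, n - min_seg)
  m1 <- cs[k] / k
  m2 <- (cs[n] - cs[k]) / (n - k)
  gain <- k * m1^2 + (n - k) * m2^2   # SSE reduction up to constants
  best <- k[which.max(gain)]
  pre <- mean(total[seq_len(best)])
  post <- mean(total[(best + 1L):n])
  if (pre <= 0 || post > (1 - min_depletion) * pre) return(NULL)
  list(at = best, pre = pre, post = post)
}

# TRUE if the pre-bleach segment itself contains another sustained step
# of at least 30% of the initial level (multi-step bleaching).
.has_extra_step <- function(total, min_seg = 5L) {
  n <- length(total)
  if (n < 2L * min_seg) return(FALSE)
  cs <- cumsum(total)
  k <- seq(min_seg, n - min_seg)
  m1 <- cs[k] / k
  m2 <- (cs[n] - cs[k]) / (n - k)
  drop <- m1 - m2
  any(drop > 0.3 * mean(total[seq_len(min_seg)]))
}

#' Select smFRET traces by quality criteria
#'
#' Applies, in order: photobleach detection (change-point on total
#' intensity, requiring a single downward step depleting at least 80% of
#' the signal), blink counting (dark intervals before the bleach), the
#' signal-to-noise criterion, the frames-above-baseline count and the
#' maximum-FRET exclusion. Each rejected trace is reported with the
#' first criterion it failed; traces too short to evaluate are rejected
#' as `"unevaluable"`. Selection is per-trace, so permuting the input
#' permutes but never changes the accepted set.
#'
#' @param traces A `trace_ensemble`, or a list of `fret_trace` objects.
#' @param criteria A [qc_criteria()] object.
#' @return A `qc_result`: list with `accepted` (logical vector),
#'   `report` (one row per trace: decision, reason, SNR, blink count,
#'   bleach frame, analyzable frames) and the `criteria` used.
#' @export
qc_select <- function(traces, criteria = qc_criteria()) {
  if (inherits(traces, "trace_ensemble")) traces <- traces$traces
  stopifnot(is.list(traces), length(traces) >= 1L,
            inherits(criteria, "qc_criteria"))
  rows <- vector("list", length(traces))
  for (i in seq_along(traces)) {
    tr <- traces[[i]]
    id <- attr(tr, "trace_id")
    if (is.null(id)) id <- sprintf("t%04d", i)
    res <- .qc_one(tr, criteria)
    rows[[i]] <- cbind(data.frame(trace_id = id, stringsAsFactors = FALSE),
                       res)
  }
  report <- do.call(rbind, rows)
  structure(list(accepted = report$accepted, report = report,
                 criteria = criteria), class = "qc_result")
}

.qc_one <- function(trace, cr) {
  out <- data.frame(accepted = FALSE, reason = "unevaluable",
                    snr = NA_real_, n_blinks = NA_integer_,
                    bleach_frame = NA_integer_, frames_above_baseline = NA_integer_,
                    stringsAsFactors = FALSE)
  n <- nrow(trace)
  if (is.null(n) || n < 10L) return(out)
  total <- trace$donor + trace$acceptor
  ef <- compute_fret(trace)

  step <- .detect_step(total, cr$min_bleach_depletion)
  if (is.null(step)) { out$reason <- "no_single_step_bleach"; return(out) }
  out$bleach_frame <- step$at
  pre <- seq_len(step$at)
  live <- pre[!ef$dark[pre]]
  # evaluate extra steps on emitting frames only, so blink intervals
  # cannot masquerade as intermediate bleach levels
  if (cr$require_single_step_bleach && .has_extra_step(total[live])) {
    out$reason <- "multi_step_bleach"; return(out)
  }
  if (length(live) < 10L) { out$reason <- "unevaluable"; return(out) }

  # blink count: maximal dark runs strictly before the bleach
  dk <- rle(ef$dark[pre])
  out$n_blinks <- sum(dk$values)
  if (out$n_blinks > cr$max_blinks) { out$reason <- "too_many_blinks"; return(out) }

  out$snr <- mean(total[live]) / stats::sd(total[live])
  if (!is.finite(out$snr) || out$snr < cr$min_snr) {
    out$reason <- "low_snr"; return(out)
  }

  out$frames_above_baseline <- sum(ef$fret[live] > cr$baseline, na.rm = TRUE)
  if (out$frames_above_baseline < cr$min_frames_above_baseline) {
    out$reason <- "too_few_frames_above_baseline"; return(out)
  }

  frac_high <- mean(ef$fret[live] > cr$max_fret, na.rm = TRUE)
  if (frac_high > cr$max_fret_frac) { out$reason <- "fret_above_max"; return(out) }

  out$accepted <- TRUE
  out$reason <- "ok"
  out
}

#' @export
print.qc_result <- function(x, ...) {
  tab <- table(x$report$reason)
  cat(sprintf("<qc_result> %d/%d traces accepted\n",
              sum(x$accepted), length(x$accepted)))
  for (nm in names(tab)) cat(sprintf("  %-30s %d\n", nm, tab[[nm]]))
  invisible(x)
}
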