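# Dwell-time extraction and transition statistics.

# Run-length segments of a class sequence with durations.
.class_runs <- function(cls, durs, starts) {
  r <- rle(cls)
  ends <- cumsum(r$lengths)
  begins <- ends - r$lengths + 1L
  data.frame(cls = r$values,
             start_s = starts[begins],
             dwell_s = vapply(seq_along(begins), function(i)
               sum(durs[begins[i]:ends[i]]), numeric(1)),
             stringsAsFactors = FALSE)
}

# Bridge: merge runs of `target` separated by non-target gaps shorter
# than bridge_s (gap time is absorbed into the bridged sojourn, as in
# burst analysis where sub-resolution flickers are counted as open time).
.bridge_runs <- function(runs, target, bridge_s) {
  if (bridge_s <= 0 || nrow(runs) < 3L) return(runs)
  repeat {
    isgap <- runs$cls != target & runs$dwell_s < bridge_s &
      c(FALSE, runs$cls[-nrow(runs)] == target) &
      c(runs$cls[-1L] == target, FALSE)
    if (!any(isgap)) break
    i <- which(isgap)[1L]
    runs$dwell_s[i - 1L] <- runs$dwell_s[i - 1L] + runs$dwell_s[i] +
      runs$dwell_s[i + 1L]
    runs <- runs[-c(i, i + 1L), , drop = FALSE]
  }
  runs
}

#' Extract dwell times from paths or idealized traces
#'
#' Collapses states (or idealization labels) into aggregate classes via
#' `aggregate_map` and extracts maximal sojourn durations per class.
#' Gaps shorter than `bridge_s` inside a class are merged into the
#' surrounding sojourn - used to bridge sub-resolution flicker closures
#' when defining open bursts. The first and last sojourn of every trace
#' are flagged as right/left-censored. For idealized traces, dark
#' frames censor the sojourns they interrupt.
#'
#' @param x A `state_path`, an `idealized_trace`, or a list of either.
#' @param aggregate_map Named character vector mapping state names (or
#'   idealization labels) to class names; entries missing from the map
#'   keep their own name.
#' @param bridge_s Bridging time in seconds (>= 0).
#' @param bridge_class Class(es) whose sojourns absorb short
#'   interruptions (e.g. `"open"` for burst analysis). Default: every
#'   class, applied in order of first appearance; gap time is absorbed
#'   exactly once, so dwells still tile the analyzable duration.
#' @param frame_s Frame duration for idealized traces lacking the
#'   attribute.
#' @return A `dwell_table` data frame: `trace_id`, `class`, `start_s`,
#'   `dwell_s`, `censored`.
#' @export
extract_dwells <- function(x, aggregate_map = NULL, bridge_s = 0,
                           bridge_class = NULL, frame_s = NULL) {
  stopifnot(bridge_s >= 0)
  if (inherits(x, "state_path") || inherits(x, "idealized_trace")) x <- list(x)
  if (!is.list(x) || !length(x)) stop("empty input")
  out <- vector("list", length(x))
  for (i in seq_along(x)) {
    el <- x[[i]]
    id <- attr(el, "trace_id")
    if (is.null(id)) id <- sprintf("t%04d", i)
    if (inherits(el, "state_path")) {
      cls <- el$state
      durs <- el$dwell_s
      starts <- el$entry_s
    } else if (inherits(el, "idealized_trace")) {
      fs <- attr(el, "frame_s")
      if (is.null(fs)) fs <- frame_s
      if (is.null(fs)) stop("frame_s needed for idealized traces")
      keep <- el$label != "dark"
      if (!any(keep)) next
      cls <- el$label[keep]
      durs <- rep(fs, sum(keep))
      starts <- (el$frame[keep] - 1L) * fs
      # mark breaks across dark gaps so interrupted sojourns are censored
      gap <- c(FALSE, diff(el$frame[keep]) > 1L)
    } else stop("unsupported input type")
    if (!is.null(aggregate_map)) {
      mapped <- aggregate_map[cls]
      cls <- ifelse(is.na(mapped), cls, mapped)
    }
    if (inherits(el, "idealized_trace") && any(gap)) {
      # split into blocks at dark gaps, treat block boundaries as censored
      blk <- cumsum(gap)
      pieces <- lapply(split(seq_along(cls), blk), function(ii) {
        runs <- .class_runs(cls[ii], durs[ii], starts[ii])
        bc <- if (is.null(bridge_class)) unique(runs$cls) else bridge_class
        for (tg in bc) runs <- .bridge_runs(runs, tg, bridge_s)
        runs$censored <- seq_len(nrow(runs)) %in% c(1L, nrow(runs))
        runs
      })
      runs <- do.call(rbind, pieces)
    } else {
      runs <- .class_runs(cls, durs, starts)
      bc <- if (is.null(bridge_class)) unique(runs$cls) else bridge_class
      for (tg in bc) runs <- .bridge_runs(runs, tg, bridge_s)
      runs$censored <- seq_len(nrow(runs)) %in% c(1L, nrow(runs))
    }
    runs$trace_id <- id
    out[[i]] <- runs
  }
  out <- do.call(rbind, out)
  if (is.null(out) || !nrow(out)) stop("no dwells extracted")
  out <- data.frame(trace_id = out$trace_id, class = out$cls,
                    start_s = out$start_s, dwell_s = out$dwell_s,
                    censored = out$censored, stringsAsFactors = FALSE)
  class(out) <- c("dwell_table", "data.frame")
  out
}

#' Frequency of transitions between low- and high-FRET classes
#'
#' Counts class switches per unit analyzable time: on idealized traces,
#' switches between consecutive non-dark frames (transitions across dark
#' gaps are not counted and dark time is excluded from the denominator);
#' on simulated paths, boundaries between the low- and high-FRET state
#' classes.
#'
#' @param x An `idealized_trace`, a `state_path`, or a list of either.
#' @return List with `per_trace` (data frame: trace_id, switches,
#'   time_s, freq_per_s) and `pooled` (total switches / total time).
#' @export
transition_frequency <- function(x) {
  if (inherits(x, "state_path") || inherits(x, "idealized_trace")) x <- list(x)
  rows <- vector("list", length(x))
  for (i in seq_along(x)) {
    el <- x[[i]]
    id <- attr(el, "trace_id")
    if (is.null(id)) id <- sprintf("t%04d", i)
    if (inherits(el, "idealized_trace")) {
      fs <- attr(el, "frame_s")
      if (is.null(fs)) stop("idealized trace lacks frame_s")
      keep <- which(el$label != "dark")
      if (length(keep) < 2L) { sw <- 0L; tt <- length(keep) * fs }
      else {
        adj <- diff(el$frame[keep]) == 1L
        sw <- sum(el$state[keep[-1L]][adj] != el$state[keep[-length(keep)]][adj])
        tt <- length(keep) * fs
      }
    } else if (inherits(el, "state_path")) {
      cls_tab <- attr(el, "state_classes")
      if (is.null(cls_tab)) stop("path lacks state_classes")
      hi <- cls_tab$fret_class[match(el$state, cls_tab$name)] %in% c("high", "mid")
      sw <- sum(diff(as.integer(hi)) != 0L)
      tt <- sum(el$dwell_s)
    } else stop("unsupported input type")
    if (tt <= 0) stop("zero analyzable time in trace ", id)
    rows[[i]] <- data.frame(trace_id = id, switches = sw, time_s = tt,
                            freq_per_s = sw / tt, stringsAsFactors = FALSE)
  }
  per <- do.call(rbind, rows)
  list(per_trace = per,
       pooled = sum(per$switches) / sum(per$time_s))
}
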