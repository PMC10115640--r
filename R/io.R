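# Columnar trace I/O and run configuration files.

#' Write smFRET traces to columnar CSV
#'
#' One row per frame: `trace_id, frame, time_s, donor, acceptor`. Truth
#' annotations of synthetic traces, when present, go to a parallel
#' `<file>_truth.csv`, never mixed into the observable columns.
#'
#' @param traces A `trace_ensemble` or list of `fret_trace`s.
#' @param file Output CSV path.
#' @param truth Also write the truth table when available.
#' @return `file`, invisibly.
#' @export
write_fret_traces <- function(traces, file, truth = TRUE) {
  if (inherits(traces, "trace_ensemble")) traces <- traces$traces
  rows <- lapply(seq_along(traces), function(i) {
    tr <- traces[[i]]
    id <- attr(tr, "trace_id")
    if (is.null(id)) id <- sprintf("t%04d", i)
    data.frame(trace_id = id, frame = tr$frame, time_s = tr$time_s,
               donor = tr$donor, acceptor = tr$acceptor)
  })
  utils::write.csv(do.call(rbind, rows), file, row.names = FALSE)
  if (truth) {
    tr_rows <- lapply(seq_along(traces), function(i) {
      tt <- attr(traces[[i]], "truth")
      if (is.null(tt)) return(NULL)
      id <- attr(traces[[i]], "trace_id")
      if (is.null(id)) id <- sprintf("t%04d", i)
      cbind(data.frame(trace_id = id), tt)
    })
    tr_rows <- Filter(Negate(is.null), tr_rows)
    if (length(tr_rows))
      utils::write.csv(do.call(rbind, tr_rows),
                       sub("\\.csv$", "_truth.csv", file), row.names = FALSE)
  }
  invisible(file)
}

#' Read smFRET traces from columnar CSV
#'
#' @param file CSV written by [write_fret_traces()] (or any file with
#'   columns `trace_id, frame, time_s, donor, acceptor`).
#' @return List of `fret_trace` objects (frame duration inferred from
#'   the time column).
#' @export
read_fret_traces <- function(file) {
  d <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("trace_id", "frame", "time_s", "donor", "acceptor")
  if (!all(need %in% names(d)))
    stop("trace file must have columns: ", paste(need, collapse = ", "))
  lapply(split(d, d$trace_id), function(g) {
    g <- g[order(g$frame), ]
    fs <- if (nrow(g) > 1L) stats::median(diff(g$time_s)) else NA_real_
    structure(g[, c("frame", "time_s", "donor", "acceptor")],
              class = c("fret_trace", "data.frame"),
              trace_id = g$trace_id[1L], frame_s = fs)
  })
}

#' Write a current trace to CSV
#' @param trace A `current_trace`.
#' @param file Output CSV (`time_s, pA`).
#' @return `file`, invisibly.
#' @export
write_current_trace <- function(trace, file) {
  utils::write.csv(as.data.frame(trace)[, c("time_s", "pA")], file,
                   row.names = FALSE)
  invisible(file)
}

#' Read a model/rate configuration file
#'
#' YAML or JSON with blocks `variant`, `rates` (per-key values in 1/s,
#' or 1/M/s for the second-order constants), and `protocol` (either
#' `atp_molar` + `duration_s`, or a list of `[start_s, atp_molar]`
#' pairs plus `duration_s`; optional `phosphorylated`).
#'
#' @param file Path to a `.yaml`/`.yml` or `.json` file.
#' @return List with `graph` (a `state_graph`) and `protocol`.
#' @export
read_rate_config <- function(file) {
  cfg <- if (grepl("\\.ya?ml$", file)) yaml::read_yaml(file)
         else jsonlite::read_json(file, simplifyVector = TRUE)
  variant <- if (is.null(cfg$variant)) "WT" else cfg$variant
  phos <- if (is.null(cfg$protocol$phosphorylated)) TRUE
          else isTRUE(cfg$protocol$phosphorylated)
  graph <- build_topology(variant, overrides = cfg$rates,
                          phosphorylated = phos)
  proto <- NULL
  if (!is.null(cfg$protocol)) {
    sched <- cfg$protocol$atp_schedule
    atp <- if (!is.null(sched)) {
      m <- do.call(rbind, lapply(sched, function(p) unlist(p)))
      data.frame(start_s = m[, 1L], atp_molar = m[, 2L])
    } else cfg$protocol$atp_molar
    proto <- protocol(atp, duration_s = cfg$protocol$duration_s,
                      phosphorylated = phos)
  }
  list(graph = graph, protocol = proto)
}
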