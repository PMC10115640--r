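# FRET efficiency computation.

#' Per-frame FRET efficiency
#'
#' Computes `E = I_A / (I_A + I_D)` from the donor and acceptor
#' intensities of a trace. Frames whose total intensity falls at or below
#' a dark threshold (donor bleached or blinked: both channels at
#' background) are flagged `dark` and their efficiency is `NA` rather
#' than a number, since the ratio is undefined without signal.
#'
#' @param trace A `fret_trace`, or a data frame with columns `donor` and
#'   `acceptor` of equal length.
#' @param dark_threshold Total-intensity level at or below which a frame
#'   is dark. Default: 30% of the 98th percentile of total intensity,
#'   which separates the (bimodal) emitting and dark levels whenever at
#'   least a few percent of frames are emitting, while staying several
#'   noise standard deviations away from both levels.
#' @return Data frame `frame`, `time_s` (when available), `fret`, `dark`.
#' @export
compute_fret <- function(trace, dark_threshold = NULL) {
  stopifnot(is.data.frame(trace),
            all(c("donor", "acceptor") %in% names(trace)))
  if (length(trace$donor) != length(trace$acceptor))
    stop("donor and acceptor channels differ in length")
  total <- trace$donor + trace$acceptor
  if (is.null(dark_threshold))
    dark_threshold <- max(0, 0.3 * stats::quantile(total, 0.98, names = FALSE))
  dark <- total <= dark_threshold
  fret <- ifelse(dark, NA_real_, trace$acceptor / total)
  out <- data.frame(frame = if ("frame" %in% names(trace)) trace$frame
                            else seq_along(total),
                    fret = fret, dark = dark)
  if ("time_s" %in% names(trace)) out$time_s <- trace$time_s
  attr(out, "dark_threshold") <- dark_threshold
  attr(out, "trace_id") <- attr(trace, "trace_id")
  attr(out, "frame_s") <- attr(trace, "frame_s")
  out
}
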