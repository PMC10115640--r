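# Fluorophore emission model for synthetic smFRET traces.

#' smFRET emission model
#'
#' Parameters of the camera-level emission process used to render
#' simulated state paths into donor/acceptor intensity traces. FRET-class
#' means default to the values characteristic of the labelled channel:
#' the NBD-separated (low-FRET) state sits at 0.25 in the apo
#' dephosphorylated channel and shifts to 0.28 once ATP is bound or the
#' channel is phosphorylated (a local rearrangement, not NBD approach);
#' the NBD-dimerized state emits at 0.49; variants that only reach an
#' intermediate NBD approach emit at 0.37 (G551D) or 0.31 (L927P).
#' Intensity noise is Gaussian and placed on the two detection channels
#' (not on the efficiency), so a signal-to-noise criterion on total
#' intensity is meaningful. Donor photobleaching is a single exponential
#' step that silences both channels; donor blinking transiently silences
#' both channels (no sensitized acceptor emission without an excited
#' donor).
#'
#' @param frame_ms Camera integration period, 10 or 100 ms.
#' @param atp_bound Logical: is ATP present in the condition? Shifts the
#'   low-FRET mean from 0.25 to 0.28.
#' @param phosphorylated Logical; phosphorylated channels also show the
#'   0.28 low-FRET mean even without nucleotide.
#' @param variant Variant name; selects the mid-FRET mean.
#' @param total_intensity Mean total (donor + acceptor) intensity in
#'   camera counts.
#' @param intensity_noise_sd Per-channel Gaussian noise sd (counts).
#' @param donor_bleach_mean_s Mean of the exponential donor bleach time.
#' @param blink_rate_per_s Poisson rate of donor blink events.
#' @param blink_mean_dur_s Mean blink duration (exponential).
#' @param fret_means Optional named override, e.g.
#'   `c(low = 0.25, mid = 0.37, high = 0.49)`.
#' @return An `emission_model` list.
#' @export
emission_model <- function(frame_ms = 100, atp_bound = TRUE,
                           phosphorylated = TRUE, variant = "WT",
                           total_intensity = 500, intensity_noise_sd = 25,
                           donor_bleach_mean_s = 30,
                           blink_rate_per_s = 0.05, blink_mean_dur_s = 0.3,
                           fret_means = NULL) {
  if (!frame_ms %in% c(10, 100))
    stop("frame_ms must be 10 or 100 (camera integration periods)")
  low <- if (atp_bound || phosphorylated) 0.28 else 0.25
  mid <- switch(variant, G551D = 0.37, L927P = 0.31, 0.37)
  means <- c(low = low, mid = mid, high = 0.49)
  if (!is.null(fret_means)) means[names(fret_means)] <- fret_means
  if (any(means <= 0) || any(means >= 1))
    stop("FRET means must lie in (0, 1)")
  if (intensity_noise_sd < 0) stop("intensity noise sd must be >= 0")
  structure(list(fret_means = means, total_intensity = total_intensity,
                 intensity_noise_sd = intensity_noise_sd,
                 frame_ms = frame_ms,
                 donor_bleach_mean_s = donor_bleach_mean_s,
                 blink_rate_per_s = blink_rate_per_s,
                 blink_mean_dur_s = blink_mean_dur_s),
            class = "emission_model")
}

# Requested signal-to-noise ratio implied by an emission model:
# mean total intensity over the sd of total intensity (two channels).
.emission_snr <- function(emission) {
  emission$total_intensity / (sqrt(2) * emission$intensity_noise_sd)
}
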