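# End-to-end reproducible runs: simulate -> render -> QC/idealize ->
# analyze -> report.

#' Pipeline run configuration
#'
#' A fully serializable description of an end-to-end run. The MD5 hash
#' of its canonical JSON serialization is embedded in every output file
#' for provenance.
#'
#' @param variant Variant preset name.
#' @param atp_molar ATP concentration held for the run.
#' @param duration_s Per-trace duration.
#' @param n_traces Ensemble size.
#' @param phosphorylated Phosphorylation state.
#' @param frame_ms Camera integration period.
#' @param seed Master seed.
#' @param emission_overrides Named list forwarded to [emission_model()].
#' @param qc_overrides Named list forwarded to [qc_criteria()].
#' @param out_dir Output directory.
#' @return A `run_config` list.
#' @export
run_config <- function(variant = "WT", atp_molar = 3e-3, duration_s = 60,
                       n_traces = 100, phosphorylated = TRUE,
                       frame_ms = 100, seed = 1L,
                       emission_overrides = list(),
                       qc_overrides = list(), out_dir = tempfile("cftr_run_")) {
  structure(list(variant = variant, atp_molar = atp_molar,
                 duration_s = duration_s, n_traces = n_traces,
                 phosphorylated = phosphorylated, frame_ms = frame_ms,
                 seed = as.integer(seed),
                 emission_overrides = emission_overrides,
                 qc_overrides = qc_overrides, out_dir = out_dir),
            class = "run_config")
}

.stage_log <- function(stage, t0, seed) {
  message(sprintf("[%s] seed=%d elapsed=%.2fs", stage, seed,
                  as.numeric(Sys.time()) - t0))
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> render -> QC -> idealize -> dwell/dose/relaxation
#' analysis from a single [run_config()], writing a report bundle
#' (observables, histogram, dwell table, QC report, fit summaries and a
#' provenance log) into the configured output directory. Re-running the
#' same configuration reproduces every numeric output bit-for-bit. A
#' failure in any stage aborts with the stage name; outputs of completed
#' stages are preserved.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the in-memory results and `out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  # hash the scientific configuration only, so runs into different
  # directories compare equal
  hash <- .config_hash(unclass(config)[setdiff(names(config), "out_dir")])
  t0 <- as.numeric(Sys.time())
  stage <- "setup"
  result <- list(config = config, config_hash = hash)
  tryCatch({
    stage <- "model"
    graph <- build_topology(config$variant,
                            phosphorylated = config$phosphorylated)
    obs <- suppressWarnings(observable_vector(graph))
    jsonlite::write_json(
      c(list(config_hash = hash),
        obs[c("po", "pdim", "coupling_ratio", "dwell_ratio",
              "tau_opening_s", "tau_sep_fast_s", "tau_sep_slow_s",
              "ec50_open_M", "ec50_dim_M", "turnover_per_s")]),
      file.path(config$out_dir, "observables.json"),
      auto_unbox = TRUE, digits = NA)
    utils::write.csv(cbind(config_hash = hash, obs$dose),
                     file.path(config$out_dir, "dose_response.csv"),
                     row.names = FALSE)
    result$observables <- obs
    .stage_log(stage, t0, config$seed)

    stage <- "simulate_render"
    proto <- protocol(config$atp_molar, config$duration_s,
                      phosphorylated = config$phosphorylated)
    emission <- do.call(emission_model, c(
      list(frame_ms = config$frame_ms,
           atp_bound = config$atp_molar > 0,
           phosphorylated = config$phosphorylated,
           variant = config$variant),
      config$emission_overrides))
    ens <- generate_ensemble(graph, proto, config$n_traces,
                             emission = emission, seed = config$seed)
    result$ensemble <- ens
    .stage_log(stage, t0, config$seed)

    stage <- "qc_idealize"
    criteria <- do.call(qc_criteria, config$qc_overrides)
    ideal <- idealize_ensemble(ens, criteria = criteria)
    utils::write.csv(cbind(config_hash = hash, ideal$qc$report),
                     file.path(config$out_dir, "qc_report.csv"),
                     row.names = FALSE)
    if (!length(ideal$idealized))
      stop("no traces survived quality control")
    lab_rows <- do.call(rbind, lapply(ideal$idealized, function(tr)
      data.frame(trace_id = attr(tr, "trace_id"), frame = tr$frame,
                 state_label = tr$label)))
    utils::write.csv(cbind(config_hash = hash, lab_rows),
                     file.path(config$out_dir, "idealization.csv"),
                     row.names = FALSE)
    result$idealized <- ideal
    .stage_log(stage, t0, config$seed)

    stage <- "analyze"
    hist_out <- ensemble_histogram(ideal$idealized)
    utils::write.csv(
      data.frame(config_hash = hash, bin_mid = hist_out$bin_mid,
                 density_mean = hist_out$density_mean,
                 density_se = hist_out$density_se),
      file.path(config$out_dir, "fret_histogram.csv"), row.names = FALSE)
    means <- ensemble_state_means(ideal$idealized)
    dw <- extract_dwells(ideal$idealized)
    utils::write.csv(cbind(config_hash = hash, as.data.frame(dw)),
                     file.path(config$out_dir, "dwells.csv"),
                     row.names = FALSE)
    tf <- transition_frequency(ideal$idealized)
    fits <- list(config_hash = hash,
                 state_means = means$by_state,
                 principal_state_mean = means$principal_mean,
                 high_fret_occupancy = hist_out$high_fret_occupancy,
                 transition_freq_per_s = tf$pooled,
                 n_hydrolysis_events = sum(vapply(ens$paths, function(p)
                   length(attr(p, "hydrolysis_events")), numeric(1))))
    jsonlite::write_json(fits, file.path(config$out_dir, "analysis.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    result$analysis <- fits
    result$histogram <- hist_out
    .stage_log(stage, t0, config$seed)

    stage <- "provenance"
    jsonlite::write_json(
      list(config = unclass(config)[setdiff(names(config), "out_dir")],
           config_hash = hash,
           package_version = as.character(utils::packageVersion("cftrgate")),
           r_version = R.version.string),
      file.path(config$out_dir, "provenance.json"),
      auto_unbox = TRUE, digits = NA, force = TRUE)
  }, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  invisible(result)
}

#' Render figures from a pipeline report bundle
#'
#' Produces the standard four panels from the CSV/JSON outputs of
#' [run_pipeline()]: population FRET histogram, dwell-time survival
#' curves, ATP dose-response with Hill fits, and the model relaxations.
#' Every figure is drawn exclusively from numbers present in the CSVs;
#' missing sections are skipped with a warning.
#'
#' @param bundle_dir Output directory of a completed run.
#' @param format Image format (`"png"` or `"pdf"`).
#' @return Character vector of figure file paths written.
#' @export
make_figures <- function(bundle_dir, format = "png") {
  stopifnot(dir.exists(bundle_dir))
  out <- character(0)
  save_fig <- function(p, name) {
    f <- file.path(bundle_dir, paste0(name, ".", format))
    ggplot2::ggsave(f, p, width = 5, height = 3.5, dpi = 150)
    out <<- c(out, f)
  }
  hf <- file.path(bundle_dir, "fret_histogram.csv")
  if (file.exists(hf)) {
    h <- utils::read.csv(hf)
    p <- ggplot2::ggplot(h, ggplot2::aes(x = bin_mid, y = density_mean)) +
      ggplot2::geom_col(fill = "grey40", width = min(diff(h$bin_mid))) +
      ggplot2::labs(x = "FRET efficiency", y = "density") +
      ggplot2::theme_classic()
    save_fig(p, "fret_histogram")
  } else warning("histogram section missing; skipped")
  df <- file.path(bundle_dir, "dwells.csv")
  if (file.exists(df)) {
    d <- utils::read.csv(df)
    # prefer complete sojourns; fall back to all when every dwell is censored
    if (any(!d$censored)) d <- d[!d$censored, ]
    if (nrow(d)) {
      surv <- do.call(rbind, lapply(split(d, d$class), function(g) {
        tt <- sort(g$dwell_s)
        data.frame(class = g$class[1L], dwell_s = tt,
                   surv = 1 - seq_along(tt) / (length(tt) + 1L))
      }))
      p <- ggplot2::ggplot(surv, ggplot2::aes(dwell_s, surv, colour = class)) +
        ggplot2::geom_step() + ggplot2::scale_y_log10() +
        ggplot2::labs(x = "dwell (s)", y = "survival") +
        ggplot2::theme_classic()
      save_fig(p, "dwell_survival")
    }
  } else warning("dwell section missing; skipped")
  dr <- file.path(bundle_dir, "dose_response.csv")
  if (file.exists(dr)) {
    d <- utils::read.csv(dr)
    dl <- rbind(data.frame(atp_M = d$atp_M, value = d$po, what = "open"),
                data.frame(atp_M = d$atp_M, value = d$pdim, what = "dimerized"))
    p <- ggplot2::ggplot(dl, ggplot2::aes(atp_M, value, colour = what)) +
      ggplot2::geom_point() + ggplot2::geom_line() +
      ggplot2::scale_x_log10() +
      ggplot2::labs(x = "[ATP] (M)", y = "probability") +
      ggplot2::theme_classic()
    save_fig(p, "dose_response")
  } else warning("dose-response section missing; skipped")
  ob <- file.path(bundle_dir, "observables.json")
  if (file.exists(ob)) {
    o <- jsonlite::read_json(ob)
    lab <- data.frame(
      what = c("tau_opening_s", "tau_sep_fast_s", "tau_sep_slow_s"),
      value = c(o$tau_opening_s, o$tau_sep_fast_s, o$tau_sep_slow_s))
    p <- ggplot2::ggplot(lab, ggplot2::aes(what, value)) +
      ggplot2::geom_col(fill = "grey40") + ggplot2::scale_y_log10() +
      ggplot2::labs(x = NULL, y = "time constant (s)") +
      ggplot2::theme_classic()
    save_fig(p, "relaxation_constants")
  } else warning("observables section missing; skipped")
  out
}
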