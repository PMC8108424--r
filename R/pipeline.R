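# End-to-end pipeline: simulate -> preprocess -> features -> spectral ->
# statistics, with a deterministic report bundle on disk.

#' Analyze one recording end to end
#'
#' Re-references, epochs, folds polarity, builds and subtracts the
#' conditioning template, extracts paired-pulse-ratio curves and refractory
#' periods, latency shifts, and (for segment montages) resting beta power
#' per channel.
#'
#' @param rec an `lfp_recording` (stimulation session, optionally with a
#'   resting prologue declared in `meta$rest_duration_s`).
#' @param window epoch window, ms.
#' @param min_template_isi template ISI threshold, ms.
#' @param beta_band Hz pair for resting band power.
#' @return list: `montage`, per-channel `results` (each with `template`,
#'   `profile_r1`, `profile_erna`, `arp`, `rrp`, `shifts`, `noise_sd`,
#'   optionally `beta_power`), and `association` when >= 3 channels.
#' @export
analyze_recording <- function(rec, window = c(-5, 16),
                              min_template_isi = 20, beta_band = c(14, 30)) {
  segmented <- sum(rec$channels$role == "segment_record") >= 3
  reref <- rereference(rec, if (segmented) "common_average_segments"
                       else "bipolar_rings")
  rest_s <- rec$meta$rest_duration_s %||% 0
  results <- lapply(seq_len(nrow(reref$channels)), function(k) {
    ep <- extract_epochs(reref, window, channel = k)
    comp <- fold_polarity(ep)
    templ <- build_template(comp, min_isi = min_template_isi)
    noise_sd <- estimate_noise_sd(templ$waveform, templ$t_ms)
    # montage orientation is arbitrary; phase-reversed channels (common on
    # directional leads) are flipped so the R1 peak is positive
    if (!detect_r1(templ$waveform, templ$t_ms, noise_sd)$present &&
        detect_r1(-templ$waveform, templ$t_ms, noise_sd)$present) {
      comp$waveforms <- -comp$waveforms
      templ$waveform <- -templ$waveform
    }
    test <- subtract_template(comp, templ)
    pr1 <- ppr_curve(test, templ, "r1")
    per <- ppr_curve(test, templ, "erna")
    out <- list(channel = reref$channels$label[k], template = templ,
                noise_sd = noise_sd,
                profile_r1 = pr1, profile_erna = per,
                arp = estimate_arp(pr1), rrp = estimate_rrp(pr1),
                shifts = latency_shifts(test, templ, noise_sd),
                template_r1 = detect_r1(templ$waveform, templ$t_ms, noise_sd),
                template_erna = detect_erna(templ$waveform, templ$t_ms,
                                            noise_sd))
    if (rest_s > 0.5) {
      rest_n <- floor(rest_s * reref$sample_rate)
      out$beta_power <- cwt_band_power(reref$signals[k, seq_len(rest_n)],
                                       reref$sample_rate, beta_band)
    }
    out
  })
  assoc <- NULL
  if (length(results) >= 3 && !is.null(results[[1]]$beta_power)) {
    assoc <- beta_feature_association(
      beta = vapply(results, `[[`, numeric(1), "beta_power"),
      erna_area = vapply(results, function(r) r$template_erna$area, numeric(1)),
      r1_area = vapply(results, function(r) r$template_r1$area, numeric(1)),
      channel = vapply(results, `[[`, character(1), "channel"))
  }
  list(montage = if (segmented) "common_average_segments" else "bipolar_rings",
       results = results, association = assoc)
}

# Long-format feature table for one analyzed channel.
channel_feature_table <- function(res) {
  sh <- res$shifts
  r1 <- res$profile_r1; er <- res$profile_erna
  ppr_tbl <- rbind(
    data.frame(isi_ms = r1$isis, component = "r1_area",
               ppr = r1$ppr, area_mvms = r1$area_test),
    data.frame(isi_ms = er$isis, component = "erna_area",
               ppr = er$ppr, area_mvms = er$area_test))
  ppr_tbl$channel <- res$channel
  sh$channel <- res$channel
  list(ppr = ppr_tbl, shifts = sh)
}

#' Run the full pipeline and write a report bundle
#'
#' Simulates a session (or reads one from disk), analyzes it, recomputes
#' the printed-table statistics from the packaged fixtures, and writes
#' `features.csv`, `refractory.json`, `stats.json` and `manifest.json` to
#' `out_dir`. All outputs are deterministic functions of the configuration,
#' so two runs with the same config and seed are byte-identical.
#'
#' @param cfg a [sim_config()] (ignored when `session_dir` is given).
#' @param out_dir output directory (created).
#' @param session_dir optional directory holding `session.edf` +
#'   `events.csv` to analyze instead of simulating.
#' @param write_session also write the simulated recording (EDF + events)
#'   under `out_dir/session/`.
#' @param fixtures_only skip simulation/analysis; only the fixture-derived
#'   statistics are written.
#' @param quiet suppress per-stage log lines.
#' @return (invisibly) list with `analysis`, `truth`, `stats`, `paths`.
#' @export
run_pipeline <- function(cfg = sim_config(), out_dir = tempfile("ppdbs_"),
                         session_dir = NULL, write_session = FALSE,
                         fixtures_only = FALSE, quiet = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_ <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
  truth <- NULL; analysis <- NULL
  stats_out <- list(fixtures = printed_stats_json(printed_stats()))
  if (!fixtures_only) {
    if (is.null(session_dir)) {
      log_("simulate: seed %d, %d ISIs, %d pairs", cfg$seed, cfg$n_isi,
           cfg$n_isi * 2L * cfg$reps_per_polarity)
      ses <- synthesize_session(cfg)
      rec <- ses$recording; truth <- ses$truth
      if (write_session) {
        sdir <- file.path(out_dir, "session")
        dir.create(sdir, showWarnings = FALSE)
        write_recording(rec, file.path(sdir, "session.edf"),
                        file.path(sdir, "events.csv"))
        jsonlite::write_json(ground_truth_json(truth),
                             file.path(sdir, "ground_truth.json"),
                             auto_unbox = TRUE, digits = NA, pretty = TRUE)
      }
    } else {
      rec <- read_recording(file.path(session_dir, "session.edf"),
                            file.path(session_dir, "events.csv"))
    }
    log_("analyze: %d events on %d channel(s)", nrow(rec$events),
         nrow(rec$signals))
    analysis <- analyze_recording(rec)
    feats <- lapply(analysis$results, channel_feature_table)
    ppr_tbl <- feature_table(do.call(rbind, lapply(feats, `[[`, "ppr")),
                             key = c("channel", "isi_ms", "component"))
    shift_tbl <- feature_table(do.call(rbind, lapply(feats, `[[`, "shifts")),
                               key = c("channel", "isi_ms", "component"))
    export_table(ppr_tbl, file.path(out_dir, "features.csv"))
    export_table(shift_tbl, file.path(out_dir, "latency_shifts.csv"))
    refr <- lapply(analysis$results, function(r) list(
      channel = r$channel,
      arp_ms = as.numeric(r$arp), arp_run = as.numeric(attr(r$arp, "run")),
      rrp_ms = as.numeric(r$rrp), rrp_run = as.numeric(attr(r$rrp, "run")),
      facilitation_isis_ms = r$profile_erna$facilitation_isis,
      ppr_r1 = data.frame(isi_ms = r$profile_r1$isis, ppr = r$profile_r1$ppr),
      ppr_erna = data.frame(isi_ms = r$profile_erna$isis,
                            ppr = r$profile_erna$ppr)))
    jsonlite::write_json(refr, file.path(out_dir, "refractory.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    ch1 <- analysis$results[[1]]
    stats_out$session <- list(
      montage = analysis$montage,
      arp_ms = as.numeric(ch1$arp), rrp_ms = as.numeric(ch1$rrp),
      n_facilitation_isis = length(ch1$profile_erna$facilitation_isis),
      noise_sd_mv = ch1$noise_sd)
    if (!is.null(truth))
      stats_out$session$truth <- list(arp_ms = truth$arp, rrp_ms = truth$rrp,
                                      arp_detect_ms = truth$arp_detect,
                                      rrp_detect_ms = truth$rrp_detect)
    if (!is.null(analysis$association))
      stats_out$session$beta_association <-
        list(r_erna = analysis$association$r_erna,
             r_r1 = analysis$association$r_r1)
  }
  jsonlite::write_json(stats_out, file.path(out_dir, "stats.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest <- list(package = "ppdbs",
                   version = as.character(utils::packageVersion("ppdbs")),
                   seed = if (fixtures_only) NULL else cfg$seed,
                   fixtures_only = fixtures_only)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_("report written to %s", out_dir)
  invisible(list(analysis = analysis, truth = truth, stats = stats_out,
                 paths = list(out_dir = out_dir)))
}

# JSON-friendly views (drop matrices/closures, keep plain values).
printed_stats_json <- function(ps) {
  list(
    fisher_erna_by_target = list(
      counts = as.data.frame(ps$fisher_erna_by_target$counts),
      p = ps$fisher_erna_by_target$p),
    binomial_concordance = ps$binomial_concordance,
    paired_t_pd = ps$paired_t_pd,
    paired_t_et = ps$paired_t_et,
    percent_change = ps$percent_change[c("n", "mean_pct", "sd_pct")],
    evoked_summaries = ps$evoked_summaries)
}

ground_truth_json <- function(truth) {
  list(arp = truth$arp, rrp = truth$rrp, arp_detect = truth$arp_detect,
       rrp_detect = truth$rrp_detect, isis = truth$isis,
       refractory_gain = truth$refractory_gain,
       facilitation_gain = truth$facilitation_gain,
       latency_delay = truth$latency_delay, hasten = truth$hasten,
       channel_gains = truth$channel_gains,
       seed = truth$cfg$seed)
}
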