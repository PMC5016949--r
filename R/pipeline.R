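# End-to-end orchestration: simulate -> align -> qc -> summarise ->
# dynamics -> inherit, with a run manifest for provenance.

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(unclass(cfg), tmp)
  unname(tools::md5sum(tmp))
}

stage_seed <- function(seed, stage) {
  derive_seed(seed, match(stage, c("simulate", "align", "qc", "summarise",
                                   "dynamics", "inherit")) * 1000L)
}

sim_config_from <- function(cfg) {
  s <- cfg$simulate
  sim_config(sigma = s$sigma, theta = s$theta,
             frame_interval = s$frame_interval, n_frames = s$n_frames,
             noise_sd = s$noise_sd,
             channel_offset = as.numeric(s$channel_offset),
             centre_sigma = s$centre_sigma, centre_theta = s$centre_theta,
             anisotropy_mode = s$anisotropy_mode,
             inheritance_coefficient = s$inheritance_coefficient)
}

strain_specs_from <- function(cfg) {
  specs <- lapply(cfg$strains, function(s) {
    strain_spec(s$strain_id, s$a_bp, s$x_p_bp, s$x_q_bp)
  })
  stats::setNames(specs, vapply(specs, `[[`, character(1), "strain_id"))
}

qc_thresholds_from <- function(cfg) {
  q <- cfg$qc
  qc_thresholds(contrast_min_green = q$contrast_min_green,
                contrast_min_red = q$contrast_min_red,
                intensity_min_red = q$intensity_min_red,
                intensity_min_green = q$intensity_min_green,
                z_margin = q$z_margin)
}

n_frames_total <- function(videos) {
  sum(vapply(as_video_list(videos), function(v) nrow(v$frames), numeric(1)))
}

#' Run the full analysis pipeline
#'
#' Executes simulate (colocalising control + population), fine alignment
#' estimated from the control and applied to all videos, quality control,
#' per-strain distance/compaction summaries, dynamics statistics (per-video
#' anisotropy D and RV, per-strain MSCD with bootstrap baseline and plateau,
#' per-locus MSD), and the mother/daughter inheritance test. All outputs are
#' TSV/JSON under `out_dir`; the run is deterministic given (config, seed).
#'
#' @param config A `"pipeline_config"` from [load_config()], or a path to a
#'   YAML config file, or `NULL` for defaults.
#' @param out_dir Output directory (created if missing).
#' @param seed Top-level integer seed; stage sub-seeds are derived from it.
#' @return The run manifest (named list), invisibly written to
#'   `manifest.json`.
#' @export
run_pipeline <- function(config = NULL, out_dir, seed = 1L) {
  cfg <- if (inherits(config, "pipeline_config")) config
    else load_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  counts <- list()
  scfg <- sim_config_from(cfg)
  specs <- strain_specs_from(cfg)

  # --- simulate ---
  sim_seed <- stage_seed(seed, "simulate")
  coloc <- simulate_colocalising_videos(scfg, cfg$simulate$n_colocalising,
                                        seed = sim_seed)
  pop <- simulate_population(scfg, specs, n_cells = cfg$simulate$n_cells,
                             fraction_paired = cfg$simulate$fraction_paired,
                             seed = sim_seed + 1L)
  write_tracking_table(coloc, file.path(out_dir, "tracking_colocalising.tsv"))
  write_tracking_table(pop, file.path(out_dir, "tracking_population.tsv"))
  counts$simulate <- list(colocalising_frames = n_frames_total(coloc),
                          population_frames = n_frames_total(pop),
                          n_videos = length(coloc) + length(pop))

  # --- qc on the control, then fine alignment from it ---
  th <- qc_thresholds_from(cfg)
  coloc_qc <- if (isTRUE(cfg$qc$enabled)) qc_filter_videos(coloc, th)
    else list(videos = coloc, report = NULL)
  offsets <- estimate_fine_offsets(coloc_qc$videos)
  coloc_aligned <- apply_fine_offsets(coloc_qc$videos, offsets)
  err <- measurement_error(coloc_aligned)
  pop_aligned <- apply_fine_offsets(pop, offsets)
  write_report(list(offsets_nm = c(offsets$dx, offsets$dy, offsets$dz),
                    n_points = offsets$n_points,
                    mean_error_nm = err$mean_nm, sd_error_nm = err$sd_nm,
                    n_frames = err$n),
               file.path(out_dir, "alignment_report.json"))
  counts$align <- list(offset_frames = offsets$n_points)

  # --- qc on the population ---
  pop_qc <- if (isTRUE(cfg$qc$enabled)) qc_filter_videos(pop_aligned, th)
    else list(videos = pop_aligned,
              report = list(total = n_frames_total(pop_aligned),
                            kept = n_frames_total(pop_aligned),
                            removed_z = 0, removed_contrast = 0,
                            removed_intensity = 0))
  write_report(pop_qc$report[setdiff(names(pop_qc$report), "per_video")],
               file.path(out_dir, "qc_report.json"))
  write_tracking_table(pop_qc$videos,
                       file.path(out_dir, "tracking_aligned_qc.tsv"))
  counts$qc <- list(total = pop_qc$report$total, kept = pop_qc$report$kept)

  # --- per-strain summaries ---
  by_strain <- split(pop_qc$videos,
                     vapply(pop_qc$videos, `[[`, character(1), "strain_id"))
  summaries <- lapply(names(by_strain), function(sid) {
    s <- strain_summary(by_strain[[sid]], specs[[sid]],
                        bin_width_nm = cfg$pipeline$bin_width_nm)
    hist_df <- data.frame(bin_lo_nm = utils::head(s$bin_edges_nm, -1),
                          bin_hi_nm = utils::tail(s$bin_edges_nm, -1),
                          count = s$bin_counts)
    utils::write.table(hist_df,
                       file.path(out_dir, paste0("histogram_", sid, ".tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    s
  })
  names(summaries) <- names(by_strain)
  write_report(lapply(summaries, function(s) {
    s[c("strain_id", "z_effective_bp", "n_videos", "n_frames",
        "mean_distance_nm", "median_distance_nm", "compaction_of_mean",
        "mean_frame_compaction")]
  }), file.path(out_dir, "strain_summaries.json"))
  counts$summarise <- list(n_strains = length(summaries),
                           frames = sum(vapply(summaries, `[[`, numeric(1),
                                               "n_frames")))

  # --- dynamics ---
  dyn_seed <- stage_seed(seed, "dynamics")
  per_video <- do.call(rbind, lapply(pop_qc$videos, function(v) {
    vec <- locus_vectors(v)
    D <- if (nrow(vec) >= 2) anisotropy_D(vec)$D else NA_real_
    rv <- if (nrow(vec) >= 4) rv_from_video(v, mode = cfg$dynamics$rv_mode)
      else NA_real_
    data.frame(video_id = v$video_id, strain_id = v$strain_id,
               n_frames = nrow(vec), D = D, rv = rv)
  }))
  utils::write.table(per_video, file.path(out_dir, "dynamics_per_video.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  dyn_summary <- lapply(names(by_strain), function(sid) {
    series <- distance_series_list(by_strain[[sid]])
    curve <- mscd_curve(series, bin_width_s = cfg$dynamics$bin_width_s)
    bl <- tryCatch(
      bootstrap_baseline(series, n_boot = cfg$dynamics$n_boot,
                         seed = dyn_seed,
                         exclude_videos = cfg$dynamics$exclude_videos),
      error = function(e) NULL)
    plateau <- tryCatch(
      plateau_estimate(curve, t_min_s = cfg$dynamics$plateau_t_min_s),
      error = function(e) NA_real_)
    utils::write.table(as.data.frame(curve),
                       file.path(out_dir, paste0("mscd_", sid, ".tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    msd <- msd_curve(by_strain[[sid]],
                     bin_width_s = cfg$dynamics$bin_width_s,
                     channel = "green")
    utils::write.table(as.data.frame(msd),
                       file.path(out_dir, paste0("msd_green_", sid, ".tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    list(strain_id = sid,
         mscd_plateau_nm2 = plateau,
         baseline_nm2 = if (is.null(bl)) NA_real_ else bl$baseline_nm2,
         baseline_se_nm2 = if (is.null(bl)) NA_real_ else bl$se_nm2,
         mean_D = mean(per_video$D[per_video$strain_id == sid], na.rm = TRUE),
         mean_rv = mean(per_video$rv[per_video$strain_id == sid],
                        na.rm = TRUE))
  })
  write_report(dyn_summary, file.path(out_dir, "dynamics_summary.json"))
  counts$dynamics <- list(n_videos = nrow(per_video))

  # --- inheritance ---
  inh <- tryCatch(
    inheritance_test(pop_qc$videos, specs,
                     n_unrelated = cfg$inheritance$n_unrelated,
                     seed = stage_seed(seed, "inherit"),
                     statistic = cfg$inheritance$statistic),
    error = function(e) NULL)
  if (!is.null(inh)) {
    write_report(list(n_related = inh$n_related,
                      n_unrelated = inh$n_unrelated,
                      U = inh$U, p_value = inh$p_value,
                      U_signed = inh$U_signed,
                      p_value_signed = inh$p_value_signed,
                      method = inh$method),
                 file.path(out_dir, "inheritance.json"))
    utils::write.table(
      data.frame(kind = c(rep("related", inh$n_related),
                          rep("unrelated", inh$n_unrelated)),
                 log2_ratio = c(inh$related_log2_ratios,
                                inh$unrelated_log2_ratios)),
      file.path(out_dir, "inheritance_ratios.tsv"),
      sep = "\t", row.names = FALSE, quote = FALSE)
    counts$inherit <- list(n_related = inh$n_related,
                           n_unrelated = inh$n_unrelated)
  }

  manifest <- list(
    tool = "chromotrack",
    version = as.character(utils::packageVersion("chromotrack")),
    config_md5 = config_hash(cfg),
    seed = seed,
    stage_seeds = list(simulate = stage_seed(seed, "simulate"),
                       dynamics = dyn_seed,
                       inherit = stage_seed(seed, "inherit")),
    counts = counts,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  write_report(manifest, file.path(out_dir, "manifest.json"))
  invisible(manifest)
}
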