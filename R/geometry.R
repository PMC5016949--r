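# Effective genomic separation, inter-locus distances, compaction ratios and
# per-strain summaries.

#' Effective genomic separation of a two-array reporter
#'
#' The fluorescent signal of an operator array centres on the array midpoint,
#' so the effective genomic separation between the two observed spots is the
#' intragenic spacer plus half of each flanking array:
#' `z = a + 0.5 * x_p + 0.5 * x_q` (all in bp).
#'
#' @param a_bp Intragenic spacer length (bp, >= 0).
#' @param x_p_bp,x_q_bp Operator array lengths (bp, >= 0).
#' @return Effective separation in bp (vectorised).
#' @export
effective_separation <- function(a_bp, x_p_bp, x_q_bp) {
  if (any(c(a_bp, x_p_bp, x_q_bp) < 0)) {
    stop("lengths must be >= 0", call. = FALSE)
  }
  a_bp + 0.5 * x_p_bp + 0.5 * x_q_bp
}

#' @rdname effective_separation
#' @param a_kb,x_p_kb,x_q_kb The same lengths in kb.
#' @export
effective_separation_kb <- function(a_kb, x_p_kb, x_q_kb) {
  effective_separation(a_kb * 1000, x_p_kb * 1000, x_q_kb * 1000) / 1000
}

#' Per-frame 3D inter-locus distance of a video
#'
#' Euclidean distance between the aligned green and red positions at each
#' retained frame.
#'
#' @param video A [cell_video()].
#' @return Object of class `"distance_series"`: video_id, cell_id, strain_id,
#'   times (s), distances (nm).
#' @export
distance_series <- function(video) {
  stopifnot(inherits(video, "cell_video"))
  d <- as.matrix(video$frames[coord_cols("red")]) -
    as.matrix(video$frames[coord_cols("green")])
  structure(list(video_id = video$video_id, cell_id = video$cell_id,
                 strain_id = video$strain_id,
                 times = video$frames$time_s,
                 distances = if (nrow(video$frames)) sqrt(rowSums(d^2))
                   else numeric(0)),
            class = "distance_series")
}

distance_series_list <- function(videos) {
  lapply(as_video_list(videos), distance_series)
}

#' Chromatin compaction ratio
#'
#' Contour length of `alpha_bp` base pairs of B-form DNA (0.34 nm/bp) divided
#' by the measured 3D distance: `0.34 * alpha_bp / d_nm`. Values near 1 mean
#' the locus is as extended as naked B-DNA; larger values mean more compact
#' chromatin.
#'
#' @param alpha_bp Genomic separation (bp).
#' @param d_nm Measured 3D distance (nm, > 0).
#' @return Dimensionless compaction ratio (vectorised).
#' @export
compaction_ratio <- function(alpha_bp, d_nm) {
  if (any(d_nm <= 0)) stop("d_nm must be > 0", call. = FALSE)
  0.34 * alpha_bp / d_nm
}

#' Pooled and per-cell distance summary for one strain
#'
#' Pools all retained frames of a strain's videos into a fixed-width distance
#' histogram (half-open bins `[lo, hi)` starting at 0; default width 63 nm,
#' the mean measurement error), computes per-cell medians and quartiles, and
#' compaction statistics against the strain's effective genomic separation.
#' Compaction is reported both as ratio-of-means `0.34 z / mean(d)` (the
#' per-strain display value) and as the mean of per-frame ratios.
#'
#' @param videos List of [cell_video()]s of one strain.
#' @param strain_spec A [strain_spec()].
#' @param bin_width_nm Histogram bin width (nm).
#' @return Object of class `"strain_summary"`.
#' @export
strain_summary <- function(videos, strain_spec, bin_width_nm = 63) {
  videos <- as_video_list(videos)
  stopifnot(inherits(strain_spec, "strain_spec"), bin_width_nm > 0)
  series <- distance_series_list(videos)
  pooled <- unlist(lapply(series, `[[`, "distances"))
  if (length(pooled) == 0L) stop("no retained frames to summarise",
                                 call. = FALSE)
  n_bins <- floor(max(pooled) / bin_width_nm) + 1L
  edges <- seq(0, n_bins * bin_width_nm, by = bin_width_nm)
  counts <- tabulate(floor(pooled / bin_width_nm) + 1L, nbins = n_bins)
  cells <- split(series, vapply(series, `[[`, character(1), "cell_id"))
  per_cell <- do.call(rbind, lapply(names(cells), function(cid) {
    d <- unlist(lapply(cells[[cid]], `[[`, "distances"))
    q <- stats::quantile(d, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(cell_id = cid, n = length(d), q25_nm = q[1],
               median_nm = q[2], q75_nm = q[3],
               mean_nm = mean(d),
               mean_compaction = mean(compaction_ratio(
                 strain_spec$z_effective_bp, d)))
  }))
  structure(list(
    strain_id = strain_spec$strain_id,
    z_effective_bp = strain_spec$z_effective_bp,
    n_videos = length(videos), n_frames = length(pooled),
    bin_edges_nm = edges, bin_counts = counts,
    mean_distance_nm = mean(pooled),
    median_distance_nm = stats::median(pooled),
    compaction_of_mean = compaction_ratio(strain_spec$z_effective_bp,
                                          mean(pooled)),
    mean_frame_compaction = mean(compaction_ratio(strain_spec$z_effective_bp,
                                                  pooled)),
    per_cell = per_cell
  ), class = "strain_summary")
}

#' @export
print.strain_summary <- function(x, ...) {
  cat(sprintf("<strain_summary %s> z = %.1f kb, %d videos, %d frames\n",
              x$strain_id, x$z_effective_bp / 1000, x$n_videos, x$n_frames))
  cat(sprintf("  mean distance %.1f nm, median %.1f nm\n",
              x$mean_distance_nm, x$median_distance_nm))
  cat(sprintf("  compaction 0.34*z/mean(d) = %.1f (mean per-frame %.1f)\n",
              x$compaction_of_mean, x$mean_frame_compaction))
  invisible(x)
}

#' @export
plot.strain_summary <- function(x, ...) {
  mids <- utils::head(x$bin_edges_nm, -1) + diff(x$bin_edges_nm) / 2
  graphics::barplot(x$bin_counts, names.arg = round(mids), space = 0,
                    xlab = "inter-locus distance (nm)", ylab = "frames",
                    main = x$strain_id, ...)
  invisible(x)
}
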