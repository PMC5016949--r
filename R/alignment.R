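# Two-stage channel alignment on spot coordinates, measurement-error
# estimation from the colocalising control, and quality-control filtering.

#' Affine coordinate transform (coarse alignment parameters)
#'
#' Coarse channel alignment estimated from calibration targets (bead slide or
#' etched slide) consists of a translation, a magnification and a rotation.
#' Estimating these from images is out of scope here; this object carries
#' externally supplied parameters so the full two-stage flow can be applied to
#' tracked coordinates.
#'
#' @param translation 3D vector, nm.
#' @param rotation 3x3 orthonormal matrix.
#' @param magnification Positive scalar.
#' @return Object of class `"affine_transform"`.
#' @export
affine_transform <- function(translation = c(0, 0, 0),
                             rotation = diag(3), magnification = 1) {
  rotation <- as.matrix(rotation)
  if (!all(dim(rotation) == c(3L, 3L)) ||
      max(abs(crossprod(rotation) - diag(3))) > 1e-9) {
    stop("rotation must be a 3x3 orthonormal matrix (tolerance 1e-9)",
         call. = FALSE)
  }
  if (!is.numeric(magnification) || magnification <= 0) {
    stop("magnification must be > 0", call. = FALSE)
  }
  structure(list(translation = as.numeric(translation), rotation = rotation,
                 magnification = magnification),
            class = "affine_transform")
}

coord_cols <- function(channel) {
  paste0(c("x_nm_", "y_nm_", "z_nm_"), channel)
}

#' Apply an affine transform to one channel of a video
#'
#' Maps the selected channel's coordinates as
#' `p -> magnification * rotation %*% p + translation`; the other channel is
#' untouched.
#'
#' @param video A [cell_video()] (or list of them).
#' @param transform An [affine_transform()].
#' @param channel "red" (default) or "green".
#' @return Video(s) with transformed coordinates.
#' @export
apply_affine <- function(video, transform, channel = c("red", "green")) {
  channel <- match.arg(channel)
  stopifnot(inherits(transform, "affine_transform"))
  one <- function(v) {
    cc <- coord_cols(channel)
    p <- as.matrix(v$frames[cc])
    q <- transform$magnification * p %*% t(transform$rotation)
    q <- sweep(q, 2L, transform$translation, "+")
    v$frames[cc] <- q
    v
  }
  if (inherits(video, "cell_video")) one(video) else lapply(video, one)
}

#' Invert an affine transform
#' @param transform An [affine_transform()].
#' @return The inverse [affine_transform()].
#' @export
invert_affine <- function(transform) {
  affine_transform(
    translation = -t(transform$rotation) %*% transform$translation /
      transform$magnification,
    rotation = t(transform$rotation),
    magnification = 1 / transform$magnification
  )
}

red_minus_green <- function(videos) {
  videos <- as_video_list(videos)
  do.call(rbind, lapply(videos, function(v) {
    as.matrix(v$frames[coord_cols("red")]) -
      as.matrix(v$frames[coord_cols("green")])
  }))
}

#' Estimate fine alignment offsets from a colocalising control
#'
#' In the colocalising strain the true inter-channel separation is zero, so
#' any systematic red-minus-green displacement is residual chromatic
#' misalignment. The fine offset is the per-axis arithmetic mean of
#' (red - green) over all frames of all supplied videos; subtracting it from
#' the red channel is the final translation of the two-stage alignment.
#'
#' @param colocalising_videos List of QC-passing [cell_video()]s.
#' @return Object of class `"fine_offsets"`: dx, dy, dz (nm), n_points, and
#'   per-axis standard errors.
#' @export
estimate_fine_offsets <- function(colocalising_videos) {
  d <- red_minus_green(colocalising_videos)
  if (is.null(d) || nrow(d) == 0L) {
    stop("no usable frames to estimate offsets from", call. = FALSE)
  }
  m <- colMeans(d)
  se <- apply(d, 2L, stats::sd) / sqrt(nrow(d))
  structure(list(dx = m[[1]], dy = m[[2]], dz = m[[3]],
                 n_points = nrow(d),
                 se = unname(se)),
            class = "fine_offsets")
}

#' @export
print.fine_offsets <- function(x, ...) {
  cat(sprintf(
    "<fine_offsets> red-green mean offset (%.2f, %.2f, %.2f) nm from %d frames\n",
    x$dx, x$dy, x$dz, x$n_points))
  invisible(x)
}

#' Apply fine alignment offsets
#'
#' Subtracts the estimated mean red-minus-green offsets from all red-channel
#' coordinates; the green channel is untouched.
#'
#' @param videos [cell_video()] or list of them.
#' @param offsets A [fine_offsets()] result or a length-3 numeric vector.
#' @return Aligned video(s).
#' @export
apply_fine_offsets <- function(videos, offsets) {
  off <- if (inherits(offsets, "fine_offsets")) {
    c(offsets$dx, offsets$dy, offsets$dz)
  } else as.numeric(offsets)
  stopifnot(length(off) == 3L, all(is.finite(off)))
  one <- function(v) {
    cc <- coord_cols("red")
    v$frames[cc] <- sweep(as.matrix(v$frames[cc]), 2L, off, "-")
    v
  }
  if (inherits(videos, "cell_video")) one(videos) else lapply(videos, one)
}

#' Residual measurement error from a colocalising control
#'
#' After alignment, the 3D Euclidean distance between the two channels'
#' estimates of the same physical spot measures localisation plus residual
#' alignment error. Returns its mean and SD over all frames of all videos.
#'
#' @param colocalising_videos Fine-aligned, QC-passing [cell_video()]s.
#' @return List with mean_nm, sd_nm, n.
#' @export
measurement_error <- function(colocalising_videos) {
  d <- red_minus_green(colocalising_videos)
  if (is.null(d) || nrow(d) == 0L) {
    stop("no frames to measure error from", call. = FALSE)
  }
  dist <- sqrt(rowSums(d^2))
  list(mean_nm = mean(dist), sd_nm = stats::sd(dist), n = length(dist))
}

#' Quality-control thresholds
#'
#' Defaults follow the tracking-error calibration of the imaging workflow:
#' frames are rejected when either spot lies within 1 um of the stack top or
#' bottom (localisation error rises sharply there), when either channel's
#' contrast falls below 12, or when maximum spot intensity falls below 25
#' (red/mCherry) or 16 (green/GFP).
#'
#' @param contrast_min_green,contrast_min_red Minimum contrast per channel.
#' @param intensity_min_red,intensity_min_green Minimum maximum-spot-intensity
#'   per channel (camera units).
#' @param z_margin Axial exclusion margin from each stack boundary (nm).
#' @return Object of class `"qc_thresholds"`.
#' @export
qc_thresholds <- function(contrast_min_green = 12, contrast_min_red = 12,
                          intensity_min_red = 25, intensity_min_green = 16,
                          z_margin = 1000) {
  th <- list(contrast_min_green = contrast_min_green,
             contrast_min_red = contrast_min_red,
             intensity_min_red = intensity_min_red,
             intensity_min_green = intensity_min_green,
             z_margin = z_margin)
  if (any(unlist(th) < 0)) stop("QC thresholds must be >= 0", call. = FALSE)
  structure(th, class = "qc_thresholds")
}

#' Quality-control filter for one video
#'
#' Removes whole frames failing any rule, attributing each removal to the
#' first failing rule in the fixed precedence order z-margin, contrast,
#' intensity:
#' \itemize{
#'   \item z-margin: either spot's z within `z_margin` of a stack boundary;
#'   \item contrast: either channel's contrast below its minimum;
#'   \item intensity: either channel's maximum intensity below its minimum.
#' }
#'
#' @param video A [cell_video()]; `stack_range` must be known.
#' @param thresholds A [qc_thresholds()] object.
#' @return List with `video` (filtered) and `report` (total, kept, removed_z,
#'   removed_contrast, removed_intensity).
#' @export
qc_filter <- function(video, thresholds = qc_thresholds()) {
  stopifnot(inherits(video, "cell_video"), inherits(thresholds, "qc_thresholds"))
  if (any(!is.finite(video$stack_range))) {
    stop("stack_range must be known for QC filtering", call. = FALSE)
  }
  f <- video$frames
  zlo <- video$stack_range[1] + thresholds$z_margin
  zhi <- video$stack_range[2] - thresholds$z_margin
  fail_z <- f$z_nm_green < zlo | f$z_nm_green > zhi |
    f$z_nm_red < zlo | f$z_nm_red > zhi
  fail_contrast <- f$contrast_green < thresholds$contrast_min_green |
    f$contrast_red < thresholds$contrast_min_red
  fail_intensity <- f$intensity_green < thresholds$intensity_min_green |
    f$intensity_red < thresholds$intensity_min_red
  removed_z <- fail_z
  removed_contrast <- !fail_z & fail_contrast
  removed_intensity <- !fail_z & !fail_contrast & fail_intensity
  keep <- !(fail_z | fail_contrast | fail_intensity)
  video$frames <- f[keep, , drop = FALSE]
  rownames(video$frames) <- NULL
  list(video = video,
       report = list(video_id = video$video_id,
                     total = nrow(f), kept = sum(keep),
                     removed_z = sum(removed_z),
                     removed_contrast = sum(removed_contrast),
                     removed_intensity = sum(removed_intensity)))
}

#' Quality-control filter for a collection of videos
#'
#' Applies [qc_filter()] to each video; videos left with zero frames are
#' dropped from the returned collection but still counted in the report.
#'
#' @param videos List of [cell_video()]s.
#' @param thresholds A [qc_thresholds()] object.
#' @return List with `videos` (filtered) and `report` (aggregate counts plus
#'   per-video rows).
#' @export
qc_filter_videos <- function(videos, thresholds = qc_thresholds()) {
  videos <- as_video_list(videos)
  out <- lapply(videos, qc_filter, thresholds = thresholds)
  reports <- lapply(out, `[[`, "report")
  filtered <- lapply(out, `[[`, "video")
  nonempty <- vapply(filtered, function(v) nrow(v$frames) > 0L, logical(1))
  agg <- function(field) sum(vapply(reports, `[[`, numeric(1), field))
  list(videos = filtered[nonempty],
       report = list(total = agg("total"), kept = agg("kept"),
                     removed_z = agg("removed_z"),
                     removed_contrast = agg("removed_contrast"),
                     removed_intensity = agg("removed_intensity"),
                     per_video = reports))
}
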