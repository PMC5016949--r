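# Dynamics statistics: orientation anisotropy via a 2D Kolmogorov-Smirnov
# statistic in UV space, the RV coefficient of coupled locus motion, MSCD
# curves with a bootstrap between-cell baseline, and per-locus MSD.

#' Map 3D direction vectors onto the unit square (UV space)
#'
#' Area-preserving map of a direction to `(u, v)`: `u` is the full-circle
#' azimuth `(atan2(y, x) + pi) / (2 pi)` wrapped to `[0, 1)` and `v` is the
#' shifted polar cosine `(|r| - z) / (2 |r|)` in `[0, 1]`. Vectors uniformly
#' distributed on the sphere give `(u, v)` uniform on the unit square, so
#' departures from uniformity measure orientation anisotropy. Note the naive
#' single-argument arctangent form of the azimuth has range (-1/4, 1/4) and
#' cannot fill the square; the two-argument form is required for the
#' uniformity property to hold.
#'
#' A vector with `x = y = 0` (pure axial) gets `u = 0.5`; zero-length vectors
#' are rejected (single input) or dropped with a count (matrix input).
#'
#' @param v A length-3 vector or an n x 3 matrix of vectors.
#' @return For a single vector, `c(u, v)`; for a matrix, a list with `uv`
#'   (m x 2 matrix) and `n_dropped`.
#' @export
uv_map <- function(v) {
  if (is.matrix(v)) {
    stopifnot(ncol(v) == 3L)
    r <- sqrt(rowSums(v^2))
    keep <- r > 0
    n_dropped <- sum(!keep)
    v <- v[keep, , drop = FALSE]
    r <- r[keep]
    u <- ((atan2(v[, 2], v[, 1]) + pi) / (2 * pi)) %% 1
    vv <- (r - v[, 3]) / (2 * r)
    return(list(uv = cbind(u = u, v = vv), n_dropped = n_dropped))
  }
  stopifnot(length(v) == 3L)
  r <- sqrt(sum(v^2))
  if (r == 0) stop("zero-length vector has no direction", call. = FALSE)
  c(u = ((atan2(v[2], v[1]) + pi) / (2 * pi)) %% 1,
    v = (r - v[3]) / (2 * r))
}

# One-sample 2D KS statistic against the uniform distribution on the unit
# square. Evaluated at the data points over the four quadrant orientations;
# the "lower" comparisons are closed (<=), their complements open. Chunked so
# the n^2 comparison matrix never exceeds ~2e6 entries.
ks2d_uniform <- function(uv) {
  n <- nrow(uv)
  u <- uv[, 1]; v <- uv[, 2]
  chunk <- max(1L, floor(2e6 / n))
  dmax <- 0
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    le_u <- outer(u, u[idx], "<=")   # n x m
    le_v <- outer(v, v[idx], "<=")
    f_ll <- colMeans(le_u & le_v)
    f_lu <- colMeans(le_u & !le_v)
    f_ul <- colMeans(!le_u & le_v)
    f_uu <- colMeans(!le_u & !le_v)
    a_ll <- u[idx] * v[idx]
    a_lu <- u[idx] * (1 - v[idx])
    a_ul <- (1 - u[idx]) * v[idx]
    a_uu <- (1 - u[idx]) * (1 - v[idx])
    dmax <- max(dmax, abs(f_ll - a_ll), abs(f_lu - a_lu),
                abs(f_ul - a_ul), abs(f_uu - a_uu))
  }
  dmax
}

#' Orientation anisotropy statistic D
#'
#' Maps a set of inter-locus vectors to UV space and computes the one-sample
#' two-dimensional Kolmogorov-Smirnov statistic against the uniform
#' distribution: the maximum, over all data points and the four quadrant
#' orientations anchored at each point, of the absolute difference between the
#' empirical fraction in the quadrant and the quadrant's area. `D` lies in
#' [0, 1]; isotropically oriented vectors give small D (O(n^-1/2)) while a
#' maintained preferred orientation gives large D. No p-value is attached; D
#' itself is the anisotropy measure.
#'
#' @param vectors An n x 3 matrix of (red - green) inter-locus vectors.
#' @return Object of class `"anisotropy_result"`: D, n (vectors used),
#'   n_dropped (zero-length vectors skipped).
#' @export
anisotropy_D <- function(vectors) {
  if (!is.matrix(vectors)) vectors <- matrix(vectors, ncol = 3L)
  m <- uv_map(vectors)
  if (nrow(m$uv) == 0L) {
    stop("no nonzero vectors to assess anisotropy on", call. = FALSE)
  }
  structure(list(D = ks2d_uniform(m$uv), n = nrow(m$uv),
                 n_dropped = m$n_dropped),
            class = "anisotropy_result")
}

#' @export
print.anisotropy_result <- function(x, ...) {
  cat(sprintf("<anisotropy> D = %.4f over %d vectors (%d zero-length dropped)\n",
              x$D, x$n, x$n_dropped))
  invisible(x)
}

#' Per-frame inter-locus vectors of a video
#'
#' Convention: red minus green, per retained frame.
#' @param video A [cell_video()].
#' @return n x 3 matrix.
#' @export
locus_vectors <- function(video) {
  stopifnot(inherits(video, "cell_video"))
  as.matrix(video$frames[coord_cols("red")]) -
    as.matrix(video$frames[coord_cols("green")])
}

#' RV coefficient between two multivariate time series
#'
#' Multivariate generalisation of the squared Pearson correlation: with
#' column-centred T x 3 matrices X and Y and cross-covariance blocks
#' `Sxy = X'Y / (T-1)`, `RV = tr(Sxy Syx) / sqrt(tr(Sxx^2) tr(Syy^2))`,
#' in [0, 1]. Values near 1 mean the two loci track together; independence
#' gives values near 0 (decreasing with series length). The default input for
#' two tracked loci is their per-frame displacement vectors (see
#' [rv_from_video()]).
#'
#' @param X,Y Numeric matrices with equal dimensions, T >= 3 rows.
#' @return RV coefficient (scalar).
#' @export
rv_coefficient <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (!all(dim(X) == dim(Y))) stop("X and Y must match in dimension",
                                   call. = FALSE)
  if (nrow(X) < 3L) stop("need at least 3 time points", call. = FALSE)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  sxx <- crossprod(Xc); syy <- crossprod(Yc); sxy <- crossprod(Xc, Yc)
  den <- sqrt(sum(sxx^2) * sum(syy^2))
  if (den == 0) stop("zero total variance in X or Y", call. = FALSE)
  sum(sxy^2) / den
}

#' RV coefficient of a video's green and red loci
#'
#' @param video A [cell_video()].
#' @param mode "displacement" (default: per-frame displacement vectors of each
#'   locus, the motion-coupling reading) or "position" (raw centred
#'   positions).
#' @return RV coefficient (scalar).
#' @export
rv_from_video <- function(video, mode = c("displacement", "position")) {
  mode <- match.arg(mode)
  g <- as.matrix(video$frames[coord_cols("green")])
  r <- as.matrix(video$frames[coord_cols("red")])
  if (mode == "displacement") {
    g <- diff(g); r <- diff(r)
  }
  rv_coefficient(g, r)
}

# Pool all ordered within-series pairs (t_i < t_j) of f(value_j, value_i)
# against the lag tau = t_j - t_i, then bin tau into [k w, (k+1) w).
pool_pairs <- function(times_list, sq_diff_list, bin_width_s) {
  taus <- vector("list", length(times_list))
  vals <- sq_diff_list
  for (i in seq_along(times_list)) {
    t <- times_list[[i]]
    dt <- outer(t, t, "-")
    taus[[i]] <- dt[lower.tri(dt)]
  }
  tau <- unlist(taus)
  val <- unlist(vals)
  bin <- floor(tau / bin_width_s)
  agg_mean <- tapply(val, bin, mean)
  agg_n <- tapply(val, bin, length)
  agg_se <- tapply(val, bin, function(x) {
    if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else NA_real_
  })
  k <- as.numeric(names(agg_mean))
  ord <- order(k)
  data.frame(bin_centre_s = (k[ord] + 0.5) * bin_width_s,
             value = as.numeric(agg_mean)[ord],
             n_pairs = as.numeric(agg_n)[ord],
             se = as.numeric(agg_se)[ord])
}

squared_lag_diffs <- function(x) {
  # lower triangle of outer(x, x, "-") pairs row j > column i, i.e. x_j - x_i
  d <- outer(x, x, "-")
  d[lower.tri(d)]^2
}

#' Mean square change in distance (MSCD) curve
#'
#' For each video, every ordered pair of retained time points (t, t + tau)
#' contributes the squared change in inter-locus distance
#' `(d(t + tau) - d(t))^2`. Pairs are pooled across all videos (one strain)
#' and binned by the time interval tau into fixed-width bins (default 6 s,
#' bin label = bin centre), giving per-bin mean, pair count and standard
#' error. The SE treats pairs as independent, which overlapping pairs are not;
#' it is an optimistic scale bar, not a confidence interval.
#'
#' @param series A [distance_series()], a list of them, or [cell_video()]s.
#' @param bin_width_s Bin width for the time interval (s).
#' @return Object of class `"mscd_curve"`: data.frame columns bin_centre_s,
#'   mscd_nm2, n_pairs, se_nm2, with optional baseline attributes.
#' @export
mscd_curve <- function(series, bin_width_s = 6) {
  series <- as_series_list(series)
  series <- Filter(function(s) length(s$distances) >= 2L, series)
  if (length(series) == 0L) {
    stop("need at least one series with >= 2 points", call. = FALSE)
  }
  pooled <- pool_pairs(lapply(series, `[[`, "times"),
                       lapply(series, function(s) squared_lag_diffs(s$distances)),
                       bin_width_s)
  out <- data.frame(bin_centre_s = pooled$bin_centre_s,
                    mscd_nm2 = pooled$value,
                    n_pairs = pooled$n_pairs,
                    se_nm2 = pooled$se)
  structure(out, class = c("mscd_curve", "data.frame"),
            bin_width_s = bin_width_s, n_videos = length(series))
}

as_series_list <- function(series) {
  if (inherits(series, "distance_series")) return(list(series))
  if (inherits(series, "cell_video")) return(distance_series_list(series))
  if (length(series) && inherits(series[[1]], "cell_video")) {
    return(distance_series_list(series))
  }
  series
}

#' @export
print.mscd_curve <- function(x, ...) {
  cat(sprintf("<mscd_curve> %d bins of %g s from %d videos\n",
              nrow(x), attr(x, "bin_width_s"), attr(x, "n_videos")))
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (!is.null(attr(x, "baseline_nm2"))) {
    cat(sprintf("between-cell bootstrap baseline: %.1f nm^2\n",
                attr(x, "baseline_nm2")))
  }
  invisible(x)
}

#' @export
plot.mscd_curve <- function(x, ...) {
  graphics::plot(x$bin_centre_s, x$mscd_nm2, type = "b", pch = 16,
                 xlab = "time interval (s)", ylab = "MSCD (nm^2)", ...)
  graphics::arrows(x$bin_centre_s, x$mscd_nm2 - x$se_nm2,
                   x$bin_centre_s, x$mscd_nm2 + x$se_nm2,
                   angle = 90, code = 3, length = 0.02)
  bl <- attr(x, "baseline_nm2")
  if (!is.null(bl)) graphics::abline(h = bl, col = "red")
  invisible(x)
}

#' Bootstrap between-cell MSCD baseline
#'
#' Estimates the time-independent, cell-independent squared distance change by
#' bootstrapping: each draw picks a video uniformly, one of its time points
#' uniformly, then a different video and one of its time points, and
#' contributes `(d_i(t_a) - d_j(t_b))^2`. If within-cell variability explains
#' the between-cell variability, the within-cell MSCD plateau approaches this
#' baseline. `exclude_videos` supports re-estimating the baseline without
#' outlier videos (e.g. cells with unusually large separations).
#'
#' @param series Distance series collection (or videos).
#' @param n_boot Number of bootstrap draws.
#' @param seed Integer seed.
#' @param exclude_videos Character vector of video_ids to drop first.
#' @return List with baseline_nm2, se_nm2, n_boot, n_videos.
#' @export
bootstrap_baseline <- function(series, n_boot = 10000, seed = 1L,
                               exclude_videos = character()) {
  series <- as_series_list(series)
  series <- Filter(function(s) length(s$distances) >= 1L &&
                     !(s$video_id %in% exclude_videos), series)
  nv <- length(series)
  if (nv < 2L) stop("need at least 2 videos after exclusion", call. = FALSE)
  set.seed(as.integer(seed))
  vi <- sample.int(nv, n_boot, replace = TRUE)
  vj <- sample.int(nv - 1L, n_boot, replace = TRUE)
  vj <- vj + (vj >= vi)   # uniform over videos != vi
  di <- vapply(seq_len(n_boot), function(k) {
    s <- series[[vi[k]]]
    s$distances[sample.int(length(s$distances), 1L)]
  }, numeric(1))
  dj <- vapply(seq_len(n_boot), function(k) {
    s <- series[[vj[k]]]
    s$distances[sample.int(length(s$distances), 1L)]
  }, numeric(1))
  sq <- (di - dj)^2
  list(baseline_nm2 = mean(sq), se_nm2 = stats::sd(sq) / sqrt(n_boot),
       n_boot = n_boot, n_videos = nv)
}

#' Attach a bootstrap baseline to an MSCD curve
#' @param curve An [mscd_curve()].
#' @param baseline Result of [bootstrap_baseline()].
#' @return The curve with baseline attributes set.
#' @export
set_baseline <- function(curve, baseline) {
  attr(curve, "baseline_nm2") <- baseline$baseline_nm2
  attr(curve, "baseline_se_nm2") <- baseline$se_nm2
  curve
}

#' Plateau value of an MSCD curve
#'
#' Count-weighted mean of the MSCD over bins whose centre lies at or beyond
#' `t_min_s` (default 150 s, where the within-cell curve has levelled off).
#'
#' @param curve An [mscd_curve()] (or msd curve).
#' @param t_min_s Minimum bin centre (s).
#' @return Plateau estimate, nm^2.
#' @export
plateau_estimate <- function(curve, t_min_s = 150) {
  value_col <- if ("mscd_nm2" %in% names(curve)) "mscd_nm2" else "msd_nm2"
  sel <- curve$bin_centre_s >= t_min_s
  if (!any(sel)) stop("no bins at or beyond t_min_s = ", t_min_s,
                      call. = FALSE)
  stats::weighted.mean(curve[[value_col]][sel], curve$n_pairs[sel])
}

#' Mean square displacement (MSD) curve of single loci
#'
#' `MSD(tau) = mean |p(t + tau) - p(t)|^2` over all ordered within-video time
#' point pairs, pooled and binned exactly as in [mscd_curve()].
#'
#' @param positions A list of trajectories, each a list with `times` (length
#'   n) and `xyz` (n x 3 matrix, nm); or [cell_video()]s plus `channel`.
#' @param bin_width_s Bin width (s).
#' @param channel When videos are supplied: which locus, "green" or "red".
#' @return Object of class `"msd_curve"` (data.frame: bin_centre_s, msd_nm2,
#'   n_pairs, se_nm2).
#' @export
msd_curve <- function(positions, bin_width_s = 6,
                      channel = c("green", "red")) {
  channel <- match.arg(channel)
  if (inherits(positions, "cell_video")) positions <- list(positions)
  if (length(positions) && inherits(positions[[1]], "cell_video")) {
    positions <- lapply(positions, function(v) {
      list(times = v$frames$time_s,
           xyz = as.matrix(v$frames[coord_cols(channel)]))
    })
  }
  positions <- Filter(function(p) length(p$times) >= 2L, positions)
  if (length(positions) == 0L) {
    stop("need at least one trajectory with >= 2 points", call. = FALSE)
  }
  sq <- lapply(positions, function(p) {
    np <- length(p$times) * (length(p$times) - 1) / 2
    per_axis <- vapply(1:3, function(ax) squared_lag_diffs(p$xyz[, ax]),
                       numeric(np))
    rowSums(matrix(per_axis, nrow = np, ncol = 3L))
  })
  pooled <- pool_pairs(lapply(positions, `[[`, "times"), sq, bin_width_s)
  out <- data.frame(bin_centre_s = pooled$bin_centre_s,
                    msd_nm2 = pooled$value,
                    n_pairs = pooled$n_pairs,
                    se_nm2 = pooled$se)
  structure(out, class = c("msd_curve", "data.frame"),
            bin_width_s = bin_width_s, n_videos = length(positions))
}
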