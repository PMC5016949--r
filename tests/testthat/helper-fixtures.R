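# Fixture builders and independent oracles shared across test files.

# Minimal video with explicit coordinates; intensity/contrast default to
# QC-passing values.
make_video <- function(green, red, times = NULL,
                       intensity_green = 40, contrast_green = 20,
                       intensity_red = 60, contrast_red = 20,
                       video_id = "v1", cell_id = "c1", strain_id = "s1",
                       role = "unpaired", pair_id = NA_character_,
                       stack_range = c(0, 5000), frame_interval = 1) {
  green <- matrix(green, ncol = 3, byrow = FALSE)
  red <- matrix(red, ncol = 3, byrow = FALSE)
  n <- nrow(green)
  if (is.null(times)) times <- seq_len(n) - 1
  frames <- data.frame(
    time_s = times,
    x_nm_green = green[, 1], y_nm_green = green[, 2], z_nm_green = green[, 3],
    intensity_green = rep_len(intensity_green, n),
    contrast_green = rep_len(contrast_green, n),
    x_nm_red = red[, 1], y_nm_red = red[, 2], z_nm_red = red[, 3],
    intensity_red = rep_len(intensity_red, n),
    contrast_red = rep_len(contrast_red, n)
  )
  cell_video(video_id = video_id, cell_id = cell_id, strain_id = strain_id,
             role = role, pair_id = pair_id, frame_interval = frame_interval,
             stack_range = stack_range, frames = frames)
}

# A video whose frames all sit at fixed positions (constant distance).
constant_video <- function(d_nm, n = 5, ...) {
  make_video(green = matrix(rep(c(0, 0, 2500), each = n), n),
             red = matrix(rep(c(d_nm, 0, 2500), each = n), n), ...)
}

# Brute-force one-sample 2D KS statistic against uniform on the unit square:
# explicit loop over every data point and the four quadrant orientations,
# "lower" comparisons closed.
oracle_ks2d <- function(uv) {
  n <- nrow(uv)
  dmax <- 0
  for (i in seq_len(n)) {
    u0 <- uv[i, 1]
    v0 <- uv[i, 2]
    for (q in 1:4) {
      inq <- switch(q,
                    uv[, 1] <= u0 & uv[, 2] <= v0,
                    uv[, 1] <= u0 & uv[, 2] > v0,
                    uv[, 1] > u0 & uv[, 2] <= v0,
                    uv[, 1] > u0 & uv[, 2] > v0)
      area <- switch(q, u0 * v0, u0 * (1 - v0), (1 - u0) * v0,
                     (1 - u0) * (1 - v0))
      dmax <- max(dmax, abs(mean(inq) - area))
    }
  }
  dmax
}

# Random 3D unit vectors (isotropic directions) times random magnitudes.
random_vectors <- function(n, anisotropic = FALSE) {
  if (anisotropic) {
    dir <- c(1, 0, 0)
    return(outer(abs(rnorm(n, 200, 50)), dir) +
             matrix(rnorm(3 * n, 0, 5), n, 3))
  }
  v <- matrix(rnorm(3 * n), n, 3)
  v * abs(rnorm(n, 200, 50)) / sqrt(rowSums(v^2))
}

default_specs <- function() {
  list(s1 = strain_spec("s1", 60600, 10400, 10400))
}
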