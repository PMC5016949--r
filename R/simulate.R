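#' Simulation configuration for synthetic two-colour locus tracking
#'
#' Builds and validates the parameter set for the synthetic trajectory
#' generator. The generator emulates two fluorescently tagged, tethered
#' chromatin loci imaged in two colour channels: the inter-locus vector
#' follows a stationary mean-reverting (Ornstein-Uhlenbeck) process per axis,
#' the pair's midpoint follows an independent confined process, each channel
#' carries Gaussian localisation noise, and the red channel carries a constant
#' chromatic offset. Intensity and contrast covariates are drawn per frame so
#' quality-control filtering can be exercised.
#'
#' @param sigma Stationary per-axis standard deviation of the inter-locus
#'   vector fluctuation (nm). Must be > 0.
#' @param theta Relaxation time of the mean reversion (s). Must be > 0.
#' @param frame_interval Time between consecutive Z-stacks (s).
#' @param n_frames Number of frames per video (>= 2).
#' @param noise_sd Per-axis localisation noise SD, per channel (nm, >= 0).
#' @param channel_offset Constant 3D vector (nm) added to red-channel
#'   coordinates, emulating residual chromatic misalignment.
#' @param centre_sigma,centre_theta Stationary SD (nm) and relaxation time (s)
#'   of the pair midpoint's confined motion.
#' @param centre_z Mean axial position of the midpoint (nm); default centres
#'   the pair in a 0--5000 nm stack.
#' @param stack_range Axial bounds of the imaging stack, c(z_min, z_max) in nm.
#' @param intensity_green,intensity_red,contrast_green,contrast_red Named
#'   numeric vectors c(mean, sd) of the per-frame Gaussian draws for the
#'   maximum spot intensity and contrast covariates of each channel.
#' @param anisotropy_mode "isotropic" (all three axes fluctuate independently)
#'   or "fixed-direction" (the inter-locus vector keeps a constant direction
#'   and only its magnitude fluctuates), used to plant detectable orientation
#'   anisotropy.
#' @param between_cell Named numeric vector c(meanlog, sdlog) of the
#'   log-normal distribution from which each cell draws its cell-specific
#'   mean separation (nm) in [simulate_population()].
#' @param inheritance_coefficient Degree, in [0, 1], to which a daughter
#'   cell's mean separation copies its mother's.
#' @param mean_separation Cell-specific mean separation magnitude (nm) for a
#'   single video; 0 gives a zero-mean fluctuation around colocation of the
#'   tether midpoints.
#'
#' @return A validated list of class `"sim_config"`.
#' @seealso [simulate_pair_video()], [simulate_colocalising_videos()],
#'   [simulate_population()]
#' @export
sim_config <- function(sigma = 150,
                       theta = 30,
                       frame_interval = 6,
                       n_frames = 100,
                       noise_sd = 27.9,
                       channel_offset = c(0, 0, 0),
                       centre_sigma = 200,
                       centre_theta = 60,
                       centre_z = 2500,
                       stack_range = c(0, 5000),
                       intensity_green = c(mean = 40, sd = 6),
                       intensity_red = c(mean = 60, sd = 9),
                       contrast_green = c(mean = 20, sd = 2.5),
                       contrast_red = c(mean = 20, sd = 2.5),
                       anisotropy_mode = c("isotropic", "fixed-direction"),
                       between_cell = c(meanlog = log(250), sdlog = 0.35),
                       inheritance_coefficient = 0,
                       mean_separation = 0) {
  anisotropy_mode <- match.arg(anisotropy_mode)
  cfg <- list(
    sigma = sigma, theta = theta, frame_interval = frame_interval,
    n_frames = as.integer(n_frames), noise_sd = noise_sd,
    channel_offset = as.numeric(channel_offset),
    centre_sigma = centre_sigma, centre_theta = centre_theta,
    centre_z = centre_z, stack_range = as.numeric(stack_range),
    intensity_green = intensity_green, intensity_red = intensity_red,
    contrast_green = contrast_green, contrast_red = contrast_red,
    anisotropy_mode = anisotropy_mode,
    between_cell = between_cell,
    inheritance_coefficient = inheritance_coefficient,
    mean_separation = mean_separation
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  num_fields <- c(
    "sigma", "theta", "frame_interval", "noise_sd", "channel_offset",
    "centre_sigma", "centre_theta", "centre_z", "stack_range",
    "intensity_green", "intensity_red", "contrast_green", "contrast_red",
    "between_cell", "inheritance_coefficient", "mean_separation"
  )
  for (f in num_fields) {
    v <- cfg[[f]]
    if (!is.numeric(v) || anyNA(v) || any(!is.finite(v))) {
      stop("sim_config field '", f, "' must be finite numeric", call. = FALSE)
    }
  }
  stopifnot(
    "sigma must be > 0" = cfg$sigma > 0,
    "theta must be > 0" = cfg$theta > 0,
    "frame_interval must be > 0" = cfg$frame_interval > 0,
    "n_frames must be >= 2" = cfg$n_frames >= 2,
    "noise_sd must be >= 0" = cfg$noise_sd >= 0,
    "channel_offset must have length 3" = length(cfg$channel_offset) == 3,
    "stack_range must be c(z_min, z_max), z_min < z_max" =
      length(cfg$stack_range) == 2 && cfg$stack_range[1] < cfg$stack_range[2],
    "inheritance_coefficient must lie in [0, 1]" =
      cfg$inheritance_coefficient >= 0 && cfg$inheritance_coefficient <= 1,
    "mean_separation must be >= 0" = cfg$mean_separation >= 0
  )
  invisible(cfg)
}

# Exact discretisation of a stationary OU process: the conditional update
# x_{t+dt} = mu + (x_t - mu) e^{-dt/theta} + N(0, sigma^2 (1 - e^{-2 dt/theta}))
# keeps the stationary SD equal to sigma and the lag-tau autocorrelation equal
# to exp(-tau/theta) at any frame interval.
ou_series <- function(n, dt, sigma, theta, mu = 0) {
  if (sigma <= 0) return(rep(mu, n))
  phi <- exp(-dt / theta)
  x0 <- stats::rnorm(1L, 0, sigma)
  if (n == 1L) return(mu + x0)
  eps <- stats::rnorm(n - 1L, 0, sigma * sqrt(1 - phi^2))
  x <- c(x0, as.numeric(stats::filter(eps, phi, method = "recursive",
                                      init = x0)))
  mu + x
}

# Deterministic per-video sub-seed derived from the top-level seed, so a
# single integer reproduces a whole population while videos stay independent.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + index * 16807) %% 2147483647)
}

random_unit_vector <- function() {
  repeat {
    v <- stats::rnorm(3L)
    n <- sqrt(sum(v^2))
    if (n > 1e-12) return(v / n)
  }
}

# Inter-locus separation vector over n frames, one row per frame.
simulate_separation <- function(cfg, mean_separation) {
  n <- cfg$n_frames
  dt <- cfg$frame_interval
  if (cfg$anisotropy_mode == "fixed-direction") {
    # Constant direction; magnitude follows a reflected OU whose stationary
    # mean/SD match the Maxwell magnitude statistics of the isotropic case,
    # so the two modes are comparable at equal sigma.
    dir <- random_unit_vector()
    mu_m <- if (mean_separation > 0) mean_separation else
      2 * cfg$sigma * sqrt(2 / pi)
    sd_m <- cfg$sigma * sqrt(3 - 8 / pi)
    mag <- abs(ou_series(n, dt, sd_m, cfg$theta, mu = mu_m))
    return(outer(mag, dir))
  }
  mu_vec <- if (mean_separation > 0) mean_separation * random_unit_vector()
    else c(0, 0, 0)
  vapply(1:3, function(ax) ou_series(n, dt, cfg$sigma, cfg$theta, mu_vec[ax]),
         numeric(n))
}

simulate_frames <- function(cfg, separation) {
  n <- cfg$n_frames
  times <- (seq_len(n) - 1L) * cfg$frame_interval
  centre <- vapply(1:3, function(ax) {
    mu <- if (ax == 3L) cfg$centre_z else 0
    ou_series(n, cfg$frame_interval, cfg$centre_sigma, cfg$centre_theta, mu)
  }, numeric(n))
  noise_g <- matrix(stats::rnorm(3L * n, 0, cfg$noise_sd), n, 3L)
  noise_r <- matrix(stats::rnorm(3L * n, 0, cfg$noise_sd), n, 3L)
  green <- centre - separation / 2 + noise_g
  red <- centre + separation / 2 + noise_r +
    matrix(cfg$channel_offset, n, 3L, byrow = TRUE)
  data.frame(
    time_s = times,
    x_nm_green = green[, 1], y_nm_green = green[, 2], z_nm_green = green[, 3],
    intensity_green = stats::rnorm(n, cfg$intensity_green[["mean"]],
                                   cfg$intensity_green[["sd"]]),
    contrast_green = stats::rnorm(n, cfg$contrast_green[["mean"]],
                                  cfg$contrast_green[["sd"]]),
    x_nm_red = red[, 1], y_nm_red = red[, 2], z_nm_red = red[, 3],
    intensity_red = stats::rnorm(n, cfg$intensity_red[["mean"]],
                                 cfg$intensity_red[["sd"]]),
    contrast_red = stats::rnorm(n, cfg$contrast_red[["mean"]],
                                cfg$contrast_red[["sd"]])
  )
}

#' Simulate one two-colour video of a tethered locus pair
#'
#' The inter-locus vector evolves as a stationary mean-reverting process per
#' axis (stationary SD `sigma`, lag-tau autocorrelation `exp(-tau/theta)`).
#' The green spot is placed at `midpoint - vector/2` plus localisation noise;
#' the red spot at `midpoint + vector/2` plus noise plus `channel_offset`.
#' True axial positions are always recorded; frames drifting near the stack
#' boundaries are left in place for quality control to flag.
#'
#' @param config A [sim_config()] object.
#' @param seed Integer seed; identical (config, seed) reproduces the video
#'   exactly.
#' @param video_id,cell_id,strain_id,role,pair_id Metadata carried on the
#'   returned video.
#' @param mean_separation Overrides `config$mean_separation` when not `NULL`
#'   (used by [simulate_population()] for cell-specific means).
#' @return A [cell_video()] object.
#' @export
simulate_pair_video <- function(config, seed,
                                video_id = "v1", cell_id = "c1",
                                strain_id = "s1", role = "unpaired",
                                pair_id = NA_character_,
                                mean_separation = NULL) {
  validate_sim_config(config)
  if (is.null(mean_separation)) mean_separation <- config$mean_separation
  set.seed(as.integer(seed))
  sep <- simulate_separation(config, mean_separation)
  frames <- simulate_frames(config, sep)
  cell_video(video_id = video_id, cell_id = cell_id, strain_id = strain_id,
             role = role, pair_id = pair_id,
             frame_interval = config$frame_interval,
             stack_range = config$stack_range, frames = frames,
             mean_separation_nm = mean_separation)
}

#' Simulate videos of a colocalising control strain
#'
#' Emulates a control strain whose single locus is bound by both the green and
#' the red repressor fusion: the true inter-channel separation is zero, so the
#' two channels differ only by localisation noise and the constant channel
#' offset. Used to estimate fine alignment offsets and residual measurement
#' error.
#'
#' @inheritParams simulate_pair_video
#' @param n_videos Number of videos to generate.
#' @return A list of [cell_video()] objects.
#' @export
simulate_colocalising_videos <- function(config, n_videos, seed) {
  validate_sim_config(config)
  lapply(seq_len(n_videos), function(i) {
    set.seed(derive_seed(seed, i))
    sep <- matrix(0, config$n_frames, 3L)
    frames <- simulate_frames(config, sep)
    cell_video(video_id = sprintf("coloc_%04d", i),
               cell_id = sprintf("coloc_cell_%04d", i),
               strain_id = "colocalising", role = "unpaired",
               pair_id = NA_character_,
               frame_interval = config$frame_interval,
               stack_range = config$stack_range, frames = frames,
               mean_separation_nm = 0)
  })
}

#' Simulate a cell population with mother/daughter lineage structure
#'
#' Each cell draws a cell-specific mean separation from a log-normal
#' between-cell distribution (`config$between_cell`), emulating the observed
#' cell-to-cell heterogeneity in locus separation. A fraction of cells come as
#' mother/daughter pairs: the daughter's mean separation equals
#' `inheritance_coefficient * mother's + (1 - inheritance_coefficient) *`
#' a fresh population draw, so inheritance strength is tunable from none (0)
#' to complete (1).
#'
#' @inheritParams simulate_pair_video
#' @param strain_specs A list of [strain_spec()] objects (or a single one);
#'   cells are assigned to strains cyclically.
#' @param n_cells Total number of cells.
#' @param fraction_paired Fraction of cells belonging to a mother/daughter
#'   pair, in [0, 1].
#' @return A list of [cell_video()] objects tagged with role
#'   (mother/daughter/unpaired) and pair_id lineage metadata.
#' @export
simulate_population <- function(config, strain_specs, n_cells,
                                fraction_paired = 1, seed = 1L) {
  validate_sim_config(config)
  if (inherits(strain_specs, "strain_spec")) strain_specs <- list(strain_specs)
  if (length(strain_specs) == 0L) {
    stop("strain_specs must contain at least one strain", call. = FALSE)
  }
  stopifnot("fraction_paired must lie in [0, 1]" =
              fraction_paired >= 0 && fraction_paired <= 1)
  n_pairs <- floor(n_cells * fraction_paired / 2)
  n_unpaired <- n_cells - 2L * n_pairs
  ic <- config$inheritance_coefficient
  ml <- config$between_cell[["meanlog"]]
  sl <- config$between_cell[["sdlog"]]

  set.seed(derive_seed(seed, 0L))
  mother_mu <- stats::rlnorm(n_pairs, ml, sl)
  daughter_mu <- ic * mother_mu + (1 - ic) * stats::rlnorm(n_pairs, ml, sl)
  unpaired_mu <- stats::rlnorm(n_unpaired, ml, sl)

  videos <- vector("list", n_cells)
  idx <- 0L
  strain_of <- function(i) strain_specs[[(i - 1L) %% length(strain_specs) + 1L]]
  for (p in seq_len(n_pairs)) {
    sp <- strain_of(p)
    pid <- sprintf("pair_%04d", p)
    for (who in c("mother", "daughter")) {
      idx <- idx + 1L
      mu <- if (who == "mother") mother_mu[p] else daughter_mu[p]
      videos[[idx]] <- simulate_pair_video(
        config, seed = derive_seed(seed, idx),
        video_id = sprintf("v_%04d", idx),
        cell_id = sprintf("cell_%04d", idx),
        strain_id = sp$strain_id, role = who, pair_id = pid,
        mean_separation = mu
      )
    }
  }
  for (u in seq_len(n_unpaired)) {
    idx <- idx + 1L
    sp <- strain_of(n_pairs + u)
    videos[[idx]] <- simulate_pair_video(
      config, seed = derive_seed(seed, idx),
      video_id = sprintf("v_%04d", idx),
      cell_id = sprintf("cell_%04d", idx),
      strain_id = sp$strain_id, role = "unpaired",
      pair_id = NA_character_, mean_separation = unpaired_mu[u]
    )
  }
  videos
}
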