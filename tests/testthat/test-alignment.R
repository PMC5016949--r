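# Affine coarse alignment, fine offsets from the colocalising control,
# residual measurement error, and quality-control filtering.

test_that("affine transforms act on the selected channel only", {
  v <- make_video(green = c(0, 0, 2500), red = c(100, 0, 2500))
  id <- affine_transform()
  expect_equal(apply_affine(v, id, "red")$frames, v$frames)

  tr <- affine_transform(translation = c(100, 0, 0))
  shifted <- apply_affine(v, tr, "red")
  expect_equal(shifted$frames$x_nm_red, 200)
  expect_equal(shifted$frames$x_nm_green, 0)

  expect_error(affine_transform(rotation = matrix(1, 3, 3)), "orthonormal")
  expect_error(affine_transform(magnification = 0), "magnification")
})

test_that("a transform followed by its inverse restores coordinates", {
  th <- 0.3
  rot <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  tf <- affine_transform(translation = c(50, -30, 10), rotation = rot,
                         magnification = 1.02)
  v <- make_video(green = matrix(rnorm(9, 0, 100) + 2500, 3),
                  red = matrix(rnorm(9, 0, 100) + 2500, 3))
  back <- apply_affine(apply_affine(v, tf, "red"), invert_affine(tf), "red")
  expect_equal(as.matrix(back$frames[c("x_nm_red", "y_nm_red", "z_nm_red")]),
               as.matrix(v$frames[c("x_nm_red", "y_nm_red", "z_nm_red")]),
               tolerance = 1e-9)
})

test_that("fine offsets are the per-axis mean of red minus green", {
  v <- make_video(green = matrix(0, 2, 3) + c(0, 0),
                  red = cbind(c(10, 30), 0, 0))
  v$frames[c("z_nm_green", "z_nm_red")] <- 2500
  v$frames$z_nm_red <- v$frames$z_nm_red   # z equal in both channels
  off <- estimate_fine_offsets(list(v))
  expect_equal(c(off$dx, off$dy, off$dz), c(20, 0, 0))
  expect_equal(off$n_points, 2)

  noiseless <- make_video(green = c(5, 5, 2500), red = c(5, 5, 2500))
  off0 <- estimate_fine_offsets(noiseless)
  expect_equal(c(off0$dx, off0$dy, off0$dz), c(0, 0, 0))

  empty <- constant_video(10, n = 2)
  empty$frames <- empty$frames[0, ]
  expect_error(estimate_fine_offsets(list(empty)), "frames")
})

test_that("planted channel offsets are recovered and removed", {
  cfg <- sim_config(noise_sd = 25, channel_offset = c(50, -20, 80),
                    n_frames = 1000)
  vids <- simulate_colocalising_videos(cfg, 12, seed = 8)
  off <- estimate_fine_offsets(vids)
  # per-axis SE of the mean of red-green: sd = 25*sqrt(2)
  for (i in 1:3) {
    expect_lt(abs(c(off$dx, off$dy, off$dz)[i] - c(50, -20, 80)[i]),
              3 * off$se[i])
  }
  aligned <- apply_fine_offsets(vids, off)
  re <- estimate_fine_offsets(aligned)
  expect_lt(max(abs(c(re$dx, re$dy, re$dz))), 1e-9)
  # alignment reduces the mean colocalising distance
  expect_lt(measurement_error(aligned)$mean_nm,
            measurement_error(vids)$mean_nm)
})

test_that("measurement error converges to the Maxwell closed form", {
  cfg <- sim_config(noise_sd = 27.9, n_frames = 5000)
  vids <- simulate_colocalising_videos(cfg, 10, seed = 12)
  err <- measurement_error(vids)
  expect_equal(err$n, 50000)
  expect_lt(abs(err$mean_nm - 4 * 27.9 / sqrt(pi)) / (4 * 27.9 / sqrt(pi)),
            0.02)
  # noiseless, offset-free control measures exactly zero
  v0 <- make_video(green = matrix(c(1, 2, 2500), 1), red = matrix(c(1, 2, 2500), 1))
  expect_equal(measurement_error(list(v0))$mean_nm, 0)
})

test_that("qc_filter removes frames by rule precedence and conserves counts", {
  n <- 100
  set.seed(99)
  green <- cbind(rnorm(n, 0, 50), rnorm(n, 0, 50), rnorm(n, 2500, 200))
  red <- green + 10
  v <- make_video(green = green, red = red, times = seq_len(n) - 1)
  # plant violations: frames 1-3 z-margin, 4-5 contrast, 6-7 intensity;
  # frame 3 also fails contrast but precedence attributes it to z
  v$frames$z_nm_green[1] <- 500
  v$frames$z_nm_red[2] <- 4500
  v$frames$z_nm_green[3] <- 900
  v$frames$contrast_green[3] <- 5
  v$frames$contrast_green[4] <- 11.9
  v$frames$contrast_red[5] <- 2
  v$frames$intensity_red[6] <- 24.9
  v$frames$intensity_green[7] <- 15
  res <- qc_filter(v, qc_thresholds())
  expect_equal(res$report$kept, 93)
  expect_equal(res$report$removed_z, 3)
  expect_equal(res$report$removed_contrast, 2)
  expect_equal(res$report$removed_intensity, 2)
  expect_equal(with(res$report, kept + removed_z + removed_contrast +
                      removed_intensity), res$report$total)
  expect_equal(nrow(res$video$frames), 93)
})

test_that("count conservation holds across random QC inputs", {
  cfg <- sim_config(n_frames = 60, centre_sigma = 800, centre_theta = 20,
                    intensity_green = c(mean = 18, sd = 5),
                    contrast_red = c(mean = 13, sd = 3))
  for (s in 1:10) {
    v <- simulate_pair_video(cfg, seed = 100 + s)
    rep <- qc_filter(v)$report
    expect_equal(rep$kept + rep$removed_z + rep$removed_contrast +
                   rep$removed_intensity, rep$total)
  }
  vids <- lapply(1:5, function(i) simulate_pair_video(cfg, seed = 200 + i))
  agg <- qc_filter_videos(vids)$report
  expect_equal(agg$total, 300)
  expect_equal(agg$kept + agg$removed_z + agg$removed_contrast +
                 agg$removed_intensity, 300)
})
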