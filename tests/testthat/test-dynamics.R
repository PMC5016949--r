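# UV mapping, the 2D KS anisotropy statistic, RV coefficient, MSCD/MSD
# curves, bootstrap baseline and plateau estimation.

test_that("uv_map follows the full-angle azimuth / polar-cosine convention", {
  expect_equal(unname(uv_map(c(0, 0, 5))["v"]), 0)
  expect_equal(unname(uv_map(c(0, 0, -5))["v"]), 1)
  expect_equal(unname(uv_map(c(1, 0, 0))), c(0.5, 0.5))
  # pure axial vector: x = y = 0 maps to u = 0.5
  expect_equal(unname(uv_map(c(0, 0, 3))["u"]), 0.5)
  # atan2 = pi wraps to u = 0 so u stays in [0, 1)
  expect_equal(unname(uv_map(c(-1, 0, 0))["u"]), 0)
  expect_error(uv_map(c(0, 0, 0)), "zero")

  m <- uv_map(rbind(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0)))
  expect_equal(m$n_dropped, 1)
  expect_equal(nrow(m$uv), 2)
  expect_true(all(m$uv[, 1] >= 0 & m$uv[, 1] < 1))
  expect_true(all(m$uv[, 2] >= 0 & m$uv[, 2] <= 1))
})

test_that("isotropic vectors map to a uniform unit square", {
  set.seed(17)
  uv <- uv_map(random_vectors(10000))$uv
  expect_gt(suppressWarnings(ks.test(uv[, 1], "punif"))$p.value, 1e-4)
  expect_gt(suppressWarnings(ks.test(uv[, 2], "punif"))$p.value, 1e-4)
  expect_lt(chromotrack:::ks2d_uniform(uv), 0.05)
})

test_that("anisotropy D matches its worked values and the brute-force oracle", {
  expect_equal(chromotrack:::ks2d_uniform(cbind(0.5, 0.5)), 0.75)
  expect_equal(
    chromotrack:::ks2d_uniform(rbind(c(0.25, 0.25), c(0.75, 0.75))), 0.4375)
  set.seed(23)
  for (rep in 1:40) {
    n <- sample(1:200, 1)
    uv <- cbind(runif(n), runif(n))
    expect_equal(chromotrack:::ks2d_uniform(uv), oracle_ks2d(uv))
  }
  res <- anisotropy_D(rbind(c(1, 0, 0)))
  expect_equal(res$D, 0.75)   # (1,0,0) maps to (0.5, 0.5)
  expect_equal(res$n, 1)
  expect_error(anisotropy_D(matrix(0, 2, 3)), "nonzero")
})

test_that("D is stable under rotation about the optical axis", {
  # a z-rotation shifts all u by a constant modulo 1; the quadrant anchors
  # shift with the data, so D is invariant up to boundary effects that vanish
  # as O(1/sqrt(n))
  set.seed(29)
  vec <- random_vectors(300)
  d0 <- anisotropy_D(vec)$D
  for (ang in c(0.4, 1.7, 3.0)) {
    rot <- rbind(c(cos(ang), -sin(ang), 0), c(sin(ang), cos(ang), 0),
                 c(0, 0, 1))
    expect_lt(abs(anisotropy_D(vec %*% t(rot))$D - d0), 0.02)
  }
})

test_that("fixed-direction vectors score higher D than isotropic ones", {
  set.seed(37)
  d_iso <- anisotropy_D(random_vectors(400))$D
  d_fix <- anisotropy_D(random_vectors(400, anisotropic = TRUE))$D
  expect_gt(d_fix, d_iso)
})

test_that("RV coefficient has its defining properties", {
  set.seed(41)
  X <- matrix(rnorm(300), 100, 3)
  expect_equal(rv_coefficient(X, X), 1)
  rot <- qr.Q(qr(matrix(rnorm(9), 3)))
  expect_equal(rv_coefficient(X, X %*% rot), 1, tolerance = 1e-12)
  Y <- matrix(rnorm(300), 100, 3)
  expect_equal(rv_coefficient(X, Y), rv_coefficient(Y, X))
  expect_equal(rv_coefficient(X, Y %*% rot), rv_coefficient(X, Y),
               tolerance = 1e-12)
  nulls <- replicate(100, rv_coefficient(matrix(rnorm(300), 100, 3),
                                         matrix(rnorm(300), 100, 3)))
  expect_lt(mean(nulls), 0.2)
  expect_true(all(nulls >= 0 & nulls <= 1))
  expect_error(rv_coefficient(X, matrix(1, 100, 3)), "variance")
  expect_error(rv_coefficient(X[1:2, ], Y[1:2, ]), "3 time points")
})

test_that("rv_from_video couples perfectly tracking loci", {
  set.seed(43)
  g <- matrix(cumsum(rnorm(60)), 20, 3) + 2500
  v <- make_video(green = g, red = g + 100)  # rigid co-movement
  expect_equal(rv_from_video(v, "displacement"), 1)
  expect_equal(rv_from_video(v, "position"), 1)
})

test_that("MSCD enumerates ordered pairs and bins by actual lag", {
  v <- make_video(green = matrix(0, 4, 3),
                  red = cbind(c(100, 200, 100, 200), 0, 0),
                  times = 0:3)
  curve <- mscd_curve(distance_series(v), bin_width_s = 1)
  # lag 1: three pairs each (±100)^2; lag 2: two pairs of 0; lag 3: one 10000
  expect_equal(curve$mscd_nm2[curve$bin_centre_s == 1.5], 10000)
  expect_equal(curve$n_pairs[curve$bin_centre_s == 1.5], 3)
  expect_equal(curve$mscd_nm2[curve$bin_centre_s == 2.5], 0)
  expect_equal(curve$n_pairs[curve$bin_centre_s == 2.5], 2)

  const <- constant_video(150, n = 6)
  cc <- mscd_curve(const, bin_width_s = 2)
  expect_true(all(cc$mscd_nm2 == 0))
  expect_error(mscd_curve(list()), "2 points")
})

test_that("MSCD is invariant under time reversal", {
  cfg <- sim_config(n_frames = 40)
  v <- simulate_pair_video(cfg, seed = 47)
  s <- distance_series(v)
  s_rev <- s
  s_rev$distances <- rev(s$distances)
  # time stamps are equally spaced, so reversing the value order preserves
  # the multiset of (lag, squared change) pairs
  expect_equal(as.data.frame(mscd_curve(s)), as.data.frame(mscd_curve(s_rev)))
})

test_that("MSCD plateau and bootstrap baseline recover the stationary theory", {
  cfg <- sim_config(sigma = 150, theta = 30, frame_interval = 6,
                    n_frames = 150, noise_sd = 0)
  series <- lapply(1:25, function(i) {
    distance_series(simulate_pair_video(cfg, seed = 500 + i,
                                        video_id = paste0("v", i)))
  })
  curve <- mscd_curve(series, bin_width_s = 6)
  plateau <- plateau_estimate(curve, t_min_s = 150)
  theory <- 2 * 150^2 * (3 - 8 / pi)
  per_video <- vapply(series, function(s) {
    plateau_estimate(mscd_curve(list(s), 6), 150)
  }, numeric(1))
  se <- sd(per_video) / sqrt(length(per_video))
  expect_lt(abs(plateau - theory), 3 * se)
  # the rise completes on the theta timescale: half-plateau lag within a
  # factor 1.5 of theta * ln 2
  half_idx <- which(curve$mscd_nm2 >= plateau / 2)[1]
  t_half <- curve$bin_centre_s[half_idx]
  expect_lt(t_half, 1.5 * 30 * log(2) + 6)   # + one bin of slack
  bl <- bootstrap_baseline(series, n_boot = 20000, seed = 3)
  expect_lt(abs(bl$baseline_nm2 - plateau), 3 * (se + bl$se_nm2))
})

test_that("bootstrap baseline uses cross-video pairs only", {
  v1 <- constant_video(100, n = 5, video_id = "a", cell_id = "ca")
  v2 <- constant_video(200, n = 5, video_id = "b", cell_id = "cb")
  bl <- bootstrap_baseline(list(v1, v2), n_boot = 500, seed = 1)
  expect_equal(bl$baseline_nm2, 10000)
  same <- bootstrap_baseline(list(v1, constant_video(100, video_id = "c")),
                             n_boot = 200, seed = 2)
  expect_equal(same$baseline_nm2, 0)
  expect_error(bootstrap_baseline(list(v1), n_boot = 10, seed = 1),
               "2 videos")
  expect_error(bootstrap_baseline(list(v1, v2), n_boot = 10, seed = 1,
                                  exclude_videos = c("a")), "2 videos")
})

test_that("plateau estimate is the count-weighted mean beyond the cutoff", {
  curve <- structure(
    data.frame(bin_centre_s = c(100, 153, 159),
               mscd_nm2 = c(5000, 9000, 11000),
               n_pairs = c(50, 10, 10), se_nm2 = NA),
    class = c("mscd_curve", "data.frame"))
  expect_equal(plateau_estimate(curve, 150), 10000)
  curve$n_pairs <- c(50, 30, 10)
  expect_equal(plateau_estimate(curve, 150), (9000 * 30 + 11000 * 10) / 40)
  expect_equal(plateau_estimate(curve, 155), 11000)
  expect_error(plateau_estimate(curve, 1000), "beyond")
})

test_that("MSD matches the confined-motion closed form and trivial cases", {
  static <- constant_video(100, n = 6)
  ms <- msd_curve(static, bin_width_s = 2)
  expect_true(all(ms$msd_nm2 == 0))

  # pure linear drift: MSD(tau) = v^2 tau^2
  drift <- make_video(green = cbind(10 * (0:9), 0, 2500) + 0,
                      red = cbind(10 * (0:9) + 50, 0, 2500), times = 0:9)
  md <- msd_curve(drift, bin_width_s = 1, channel = "green")
  lag <- floor(md$bin_centre_s)
  expect_equal(md$msd_nm2, (10 * lag)^2)

  # confined locus: green = centre - sep/2, both independent OU processes, so
  # MSD(tau) = 6 sc^2 (1 - e^(-tau/tc)) + 6 (sigma/2)^2 (1 - e^(-tau/theta))
  cfg <- sim_config(sigma = 100, theta = 20, centre_sigma = 250,
                    centre_theta = 50, frame_interval = 5, n_frames = 200,
                    noise_sd = 0)
  vids <- lapply(1:20, function(i) simulate_pair_video(cfg, seed = 700 + i))
  md2 <- msd_curve(vids, bin_width_s = 5, channel = "green")
  lag <- md2$bin_centre_s - 2.5   # single 5-s lags per bin
  theory <- 6 * 250^2 * (1 - exp(-lag / 50)) +
    6 * 50^2 * (1 - exp(-lag / 20))
  sel <- 1:10
  expect_lt(max(abs(md2$msd_nm2[sel] / theory[sel] - 1)), 0.15)
})
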