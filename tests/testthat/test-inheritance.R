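# Log2 compaction ratios, unrelated-pair sampling, the Mann-Whitney test and
# the full mother/daughter inheritance comparison.

test_that("log2 compaction ratios follow the distance ratio", {
  specs <- default_specs()
  m <- constant_video(100, video_id = "m", cell_id = "cm", role = "mother",
                      pair_id = "p1")
  d <- constant_video(200, video_id = "d", cell_id = "cd", role = "daughter",
                      pair_id = "p1")
  expect_equal(log2_compaction_ratios(list(list(m, m)), specs), 0)
  expect_equal(log2_compaction_ratios(list(list(m, d)), specs), 1)
  # antisymmetry
  expect_equal(log2_compaction_ratios(list(list(d, m)), specs), -1)
  # alpha cancels within a strain: same ratios under a different geometry
  specs2 <- list(s1 = strain_spec("s1", 10000, 2000, 2000))
  expect_equal(log2_compaction_ratios(list(list(m, d)), specs2), 1)

  other <- constant_video(100, video_id = "x", strain_id = "s2")
  expect_error(log2_compaction_ratios(list(list(m, other)), specs),
               "strain")
})

test_that("random unrelated pairs exclude lineage pairs and reproduce under a
           seed", {
  mk <- function(i, role) {
    constant_video(100 + i, video_id = paste0(role, i),
                   cell_id = paste0("c", role, i), role = role,
                   pair_id = paste0("p", i))
  }
  mothers <- lapply(1:4, mk, role = "mother")
  daughters <- lapply(1:4, mk, role = "daughter")
  pairs <- random_unrelated_pairs(mothers, daughters, 50, seed = 13)
  expect_length(pairs, 50)
  for (p in pairs) {
    expect_false(p[[1]]$pair_id == p[[2]]$pair_id)
  }
  pairs2 <- random_unrelated_pairs(mothers, daughters, 50, seed = 13)
  expect_identical(lapply(pairs, function(p) p[[1]]$video_id),
                   lapply(pairs2, function(p) p[[1]]$video_id))
  # 1 mother + 1 related daughter: no unrelated pairing exists
  expect_error(random_unrelated_pairs(mothers[1], daughters[1], 5, seed = 1),
               "no unrelated")
  # mother/mother mode excludes self-pairs only
  mm <- random_unrelated_pairs(mothers, daughters, 30, seed = 2,
                               mode = "mother-mother")
  for (p in mm) expect_false(p[[1]]$video_id == p[[2]]$video_id)
})

test_that("Mann-Whitney exact branch matches enumeration and wilcox.test", {
  res <- mann_whitney_exact(c(1, 2), c(3, 4))
  expect_equal(res$U, 0)
  expect_equal(res$p_two_sided, 1 / 3, tolerance = 1e-12)
  expect_equal(res$method, "exact")

  # all-tie case collapses to no evidence
  tie <- mann_whitney_exact(c(5, 5, 5), c(5, 5, 5))
  expect_equal(tie$p_two_sided, 1)

  # against the independent implementation for tie-free samples, n_a+n_b <= 8
  set.seed(53)
  for (rep in 1:25) {
    na <- sample(2:4, 1)
    nb <- sample(2:4, 1)
    a <- sample(seq_len(50), na)
    b <- sample(setdiff(seq_len(50), a), nb)
    mine <- mann_whitney_exact(a, b)
    ref <- wilcox.test(a, b, exact = TRUE)
    expect_equal(mine$U, unname(ref$statistic))
    expect_equal(mine$p_two_sided, ref$p.value, tolerance = 1e-12)
  }
})

test_that("exact and normal-approximation branches agree for moderate n", {
  set.seed(59)
  for (rep in 1:10) {
    a <- rnorm(6)
    b <- rnorm(6)
    exact <- mann_whitney_exact(a, b)$p_two_sided
    # force the normal branch by padding beyond the exact-size cutoff is not
    # possible without changing the data; instead compare with the
    # tie-corrected normal approximation computed directly
    ref <- wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value
    expect_lt(abs(exact - ref), 0.02)
  }
  # ties push even small samples onto the normal branch
  tied <- mann_whitney_exact(c(1, 2, 2), c(2, 3, 4))
  expect_equal(tied$method, "normal")
  expect_true(tied$p_two_sided > 0 && tied$p_two_sided <= 1)
})

test_that("inheritance test runs end to end and respects its seed", {
  cfg <- sim_config(inheritance_coefficient = 0.5, n_frames = 10)
  pop <- simulate_population(cfg, default_specs(), n_cells = 12,
                             fraction_paired = 1, seed = 61)
  r1 <- inheritance_test(pop, default_specs(), seed = 5)
  r2 <- inheritance_test(pop, default_specs(), seed = 5)
  expect_equal(r1$p_value, r2$p_value)
  expect_equal(r1$n_related, 6)
  expect_equal(length(r1$related_log2_ratios), r1$n_related)
  expect_equal(length(r1$unrelated_log2_ratios), r1$n_unrelated)
  expect_true(r1$p_value > 0 && r1$p_value <= 1)
  expect_true(!is.null(r1$p_value_signed))
})

test_that("a single related and unrelated pair still yields a finite p", {
  cfg <- sim_config(n_frames = 5)
  pop <- simulate_population(cfg, default_specs(), n_cells = 4,
                             fraction_paired = 1, seed = 67)
  res <- inheritance_test(pop, default_specs(), n_unrelated = 1, seed = 3)
  expect_true(is.finite(res$p_value))
  expect_equal(res$n_related, 2)
})

test_that("strong inheritance shrinks related ratio magnitudes", {
  cfg <- sim_config(inheritance_coefficient = 0.95, n_frames = 50,
                    noise_sd = 27.9)
  pop <- simulate_population(cfg, default_specs(), n_cells = 80,
                             fraction_paired = 1, seed = 71)
  res <- inheritance_test(pop, default_specs(), seed = 11)
  expect_lt(median(abs(res$related_log2_ratios)),
            median(abs(res$unrelated_log2_ratios)))
})
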