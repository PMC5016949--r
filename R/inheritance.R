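# Mother/daughter chromatin-configuration inheritance test: log2 compaction
# ratios between paired cells, compared with randomly paired unrelated cells
# via a rank-sum (Mann-Whitney) test.

video_compaction <- function(video, strain_specs, statistic = "mean") {
  sp <- strain_specs[[video$strain_id]]
  if (is.null(sp)) stop("no strain spec for strain '", video$strain_id, "'",
                        call. = FALSE)
  d <- distance_series(video)$distances
  if (length(d) == 0L || any(d <= 0)) {
    stop("video '", video$video_id, "' has no usable distances",
         call. = FALSE)
  }
  ratios <- compaction_ratio(sp$z_effective_bp, d)
  if (statistic == "median") stats::median(ratios) else mean(ratios)
}

#' Log2 compaction ratios between paired videos
#'
#' For each pair (A, B) of same-strain videos, computes
#' `log2(compaction_A / compaction_B)` where a video's compaction is the mean
#' (or median) of its per-frame compaction ratios. The first element (the
#' mother, for lineage pairs) is the numerator. For same-strain pairs the
#' genomic separation cancels, so the ratio only reflects the measured
#' distances.
#'
#' @param pairs List of two-element lists/pairs of [cell_video()]s.
#' @param strain_specs Named list of [strain_spec()]s (names = strain_id).
#' @param statistic "mean" (default) or "median" per-video compaction.
#' @return Numeric vector of log2 ratios, one per pair.
#' @export
log2_compaction_ratios <- function(pairs, strain_specs, statistic = "mean") {
  if (inherits(strain_specs, "strain_spec")) {
    strain_specs <- stats::setNames(list(strain_specs),
                                    strain_specs$strain_id)
  }
  vapply(pairs, function(p) {
    a <- p[[1]]; b <- p[[2]]
    if (a$strain_id != b$strain_id) {
      stop("pair spans different strains (", a$strain_id, " vs ",
           b$strain_id, ")", call. = FALSE)
    }
    log2(video_compaction(a, strain_specs, statistic) /
           video_compaction(b, strain_specs, statistic))
  }, numeric(1))
}

#' Random unrelated cell pairs
#'
#' Draws seeded random pairs with replacement, excluding true lineage pairs
#' (same `pair_id`) and self-pairs. Modes: "mother-daughter" (default),
#' "mother-mother", "daughter-daughter".
#'
#' @param mothers,daughters Lists of [cell_video()]s.
#' @param n_pairs Number of pairs to draw.
#' @param seed Integer seed.
#' @param mode Pairing mode.
#' @return List of two-element video lists.
#' @export
random_unrelated_pairs <- function(mothers, daughters, n_pairs, seed = 1L,
                                   mode = c("mother-daughter",
                                            "mother-mother",
                                            "daughter-daughter")) {
  mode <- match.arg(mode)
  pool_a <- switch(mode, "mother-daughter" = mothers,
                   "mother-mother" = mothers, "daughter-daughter" = daughters)
  pool_b <- switch(mode, "mother-daughter" = daughters,
                   "mother-mother" = mothers, "daughter-daughter" = daughters)
  ok <- function(a, b) {
    if (a$video_id == b$video_id) return(FALSE)
    if (mode == "mother-daughter" &&
        !is.na(a$pair_id) && !is.na(b$pair_id) &&
        a$pair_id == b$pair_id) return(FALSE)
    TRUE
  }
  any_ok <- any(vapply(pool_a, function(a) {
    any(vapply(pool_b, function(b) ok(a, b), logical(1)))
  }, logical(1)))
  if (!any_ok) {
    stop("no unrelated pairing is possible with the supplied cells",
         call. = FALSE)
  }
  set.seed(as.integer(seed))
  out <- vector("list", n_pairs)
  for (k in seq_len(n_pairs)) {
    repeat {
      a <- pool_a[[sample.int(length(pool_a), 1L)]]
      b <- pool_b[[sample.int(length(pool_b), 1L)]]
      if (ok(a, b)) break
    }
    out[[k]] <- list(a, b)
  }
  out
}

#' Two-sided Mann-Whitney rank-sum test
#'
#' `U` is the rank-sum statistic of the first sample (number of (a, b) pairs
#' with a < b, counting ties as 1/2). The p-value is exact — full enumeration
#' over all rank assignments — when `n_a + n_b <= 12` and there are no ties;
#' otherwise the normal approximation with tie correction and continuity
#' correction is used. Two-sided p is `min(1, 2 min(P(U <= u), P(U >= u)))`
#' in the exact branch.
#'
#' @param sample_a,sample_b Non-empty numeric vectors.
#' @return List with U, p_two_sided, method ("exact" or "normal").
#' @export
mann_whitney_exact <- function(sample_a, sample_b) {
  if (length(sample_a) == 0L || length(sample_b) == 0L) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  na <- length(sample_a); nb <- length(sample_b); n <- na + nb
  pooled <- c(sample_a, sample_b)
  rk <- rank(pooled)
  u_obs <- sum(rk[seq_len(na)]) - na * (na + 1) / 2
  ties <- any(duplicated(pooled))
  if (n <= 12L && !ties) {
    subsets <- utils::combn(n, na)
    u_all <- colSums(matrix(subsets, nrow = na)) - na * (na + 1) / 2
    p_le <- mean(u_all <= u_obs)
    p_ge <- mean(u_all >= u_obs)
    p <- min(1, 2 * min(p_le, p_ge))
    return(list(U = u_obs, p_two_sided = p, method = "exact"))
  }
  mu <- na * nb / 2
  tie_tab <- table(pooled)
  tie_term <- sum(tie_tab^3 - tie_tab)
  sigma2 <- na * nb / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  if (sigma2 <= 0) {
    return(list(U = u_obs, p_two_sided = 1, method = "normal"))
  }
  z <- (abs(u_obs - mu) - 0.5) / sqrt(sigma2)
  p <- min(1, 2 * stats::pnorm(-max(z, 0)))
  list(U = u_obs, p_two_sided = p, method = "normal")
}

#' Mother/daughter compaction inheritance test
#'
#' Builds related mother/daughter pairs from lineage metadata and an equal
#' number (by default) of random unrelated mother/daughter pairs, computes
#' log2 compaction ratios for both sets, and compares them with a two-sided
#' Mann-Whitney test — primarily on the absolute log2 ratios (inheritance
#' shrinks the magnitude of the compaction change between related cells), with
#' the signed comparison reported alongside.
#'
#' @param videos List of [cell_video()]s carrying role and pair_id metadata.
#' @param strain_specs Named list of [strain_spec()]s.
#' @param n_unrelated Number of unrelated pairs; default = number of related
#'   pairs.
#' @param seed Integer seed for the unrelated pairing.
#' @param statistic Per-video compaction statistic, "mean" or "median".
#' @return Object of class `"inheritance_result"`.
#' @export
inheritance_test <- function(videos, strain_specs, n_unrelated = NULL,
                             seed = 1L, statistic = "mean") {
  videos <- as_video_list(videos)
  mothers <- Filter(function(v) v$role == "mother", videos)
  daughters <- Filter(function(v) v$role == "daughter", videos)
  if (length(mothers) == 0L || length(daughters) == 0L) {
    stop("need both mother and daughter videos", call. = FALSE)
  }
  dmap <- stats::setNames(daughters,
                          vapply(daughters, `[[`, character(1), "pair_id"))
  related <- list()
  for (m in mothers) {
    d <- dmap[[m$pair_id]]
    if (!is.null(d) && d$strain_id == m$strain_id) {
      related[[length(related) + 1L]] <- list(m, d)
    }
  }
  if (length(related) == 0L) stop("no related mother/daughter pairs found",
                                  call. = FALSE)
  if (is.null(n_unrelated)) n_unrelated <- length(related)
  unrelated_pairs <- random_unrelated_pairs(mothers, daughters, n_unrelated,
                                            seed = seed)
  # unrelated pairs must also be same-strain for the ratio to be meaningful
  unrelated_pairs <- Filter(function(p) p[[1]]$strain_id == p[[2]]$strain_id,
                            unrelated_pairs)
  if (length(unrelated_pairs) == 0L) {
    stop("no same-strain unrelated pairs drawn; increase n_unrelated",
         call. = FALSE)
  }
  rel <- log2_compaction_ratios(related, strain_specs, statistic)
  unrel <- log2_compaction_ratios(unrelated_pairs, strain_specs, statistic)
  test_abs <- mann_whitney_exact(abs(rel), abs(unrel))
  test_signed <- mann_whitney_exact(rel, unrel)
  structure(list(
    related_log2_ratios = rel, unrelated_log2_ratios = unrel,
    n_related = length(rel), n_unrelated = length(unrel),
    U = test_abs$U, p_value = test_abs$p_two_sided,
    method = test_abs$method,
    U_signed = test_signed$U, p_value_signed = test_signed$p_two_sided,
    seed = seed
  ), class = "inheritance_result")
}

#' @export
print.inheritance_result <- function(x, ...) {
  cat(sprintf("<inheritance_test> %d related vs %d unrelated pairs\n",
              x$n_related, x$n_unrelated))
  cat(sprintf("  |log2 ratio|: U = %g, two-sided p = %.4g (%s)\n",
              x$U, x$p_value, x$method))
  cat(sprintf("  signed:       U = %g, two-sided p = %.4g\n",
              x$U_signed, x$p_value_signed))
  invisible(x)
}
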