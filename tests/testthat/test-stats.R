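# statistical engine: summaries, richness, nuclei, ANOVA/Tukey, t-tests,
# with permutation oracles for the inferential machinery

# permutation oracle for the one-way ANOVA F test (label permutation)
perm_anova_p <- function(y, g, n_perm = 1e5) {
  g <- factor(g)
  f_stat <- function(yy) {
    m <- tapply(yy, g, mean); n <- tabulate(g)
    ssb <- sum(n * (m - mean(yy))^2)
    ssw <- sum((yy - m[g])^2)
    (ssb / (nlevels(g) - 1)) / (ssw / (length(yy) - nlevels(g)))
  }
  f0 <- f_stat(y)
  hits <- 0L
  for (i in seq_len(n_perm)) if (f_stat(sample(y)) >= f0) hits <- hits + 1L
  (hits + 1) / (n_perm + 1)
}

# sign-flip oracle for the paired t-test (exact over all 2^n flips when
# feasible, else sampled)
signflip_p <- function(d, n_perm = 1e5) {
  n <- length(d)
  t_of <- function(dd) abs(mean(dd)) / (sd(dd) / sqrt(n))
  t0 <- t_of(d)
  if (2^n <= n_perm) { # exact enumeration
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    ts <- apply(signs * rep(d, each = nrow(signs)), 1, t_of)
    return(mean(ts >= t0 - 1e-12))
  }
  hits <- 0L
  for (i in seq_len(n_perm))
    if (t_of(d * sample(c(-1, 1), n, TRUE)) >= t0 - 1e-12) hits <- hits + 1L
  (hits + 1) / (n_perm + 1)
}

test_that("printed-precision rounding reproduces published average sizes", {
  expect_equal(round_printed(27.377 / 4837), 0.006)
  expect_equal(round_printed(1.359 / 3435), 3.96e-4)
  expect_equal(round_printed(0.0005), 5e-4) # 3 sig figs below 1e-3
  expect_equal(round_printed(0.0015), 0.002)
})

test_that("significance codes follow the Prism convention", {
  expect_equal(significance_code(c(0.5, 0.04, 0.009, 0.0009, 0.00009)),
               c("ns", "*", "**", "***", "****"))
  expect_equal(significance_code(0.05), "ns")
  expect_equal(significance_code(1e-4), "***")
})

test_that("cell summaries satisfy the table identities", {
  geom <- measure_cell(rect_roi("c1", x1 = 19, y1 = 19), 0.2)
  g <- data.frame(area_px2 = c(4, 6, 5), mean_af = c(100, 120, 110),
                  volume_vox = c(8, 10, 9),
                  family = c("MELANIN", "LIPOFUSCIN", "MELANOLIPOFUSCIN"))
  s <- summarize_cell(g, geom, dose = "LOW_40", day = 1)
  expect_equal(s$count, 3)
  expect_equal(s$total_area, 15)
  expect_equal(s$average_size * s$count, s$total_area)
  expect_equal(s$percent_area, 100 * 15 / geom$area_px2)
  expect_true(s$percent_area >= 0 && s$percent_area <= 100)
  expect_equal(s$melanin_to_lipofuscin_ratio, 2)

  s0 <- summarize_cell(g[0, ], geom)
  expect_equal(s0$count, 0)
  expect_equal(s0$total_area, 0)
  expect_true(is.na(s0$average_size)) # missing, not zero
  expect_equal(s0$percent_area, 0)
})

test_that("richness labels compare against cohort medians", {
  base <- data.frame(count = c(10, 12, 14, 16, 18),
                     melanin_to_lipofuscin_ratio = c(1, 1.2, 1.4, 1.6, 1.8))
  s <- label_richness(base)
  expect_equal(s$richness[3], "GRANULE_RICH") # at both medians: rich
  poor <- rbind(base, data.frame(count = 5,
                                 melanin_to_lipofuscin_ratio = 3))
  expect_equal(label_richness(poor)$richness[6], "GRANULE_POOR")
  same <- data.frame(count = rep(8, 6),
                     melanin_to_lipofuscin_ratio = rep(1.5, 6))
  expect_true(all(label_richness(same)$richness == "GRANULE_RICH"))
})

test_that("nuclei are counted from the nuclei channel", {
  mk_nuc_stack <- function(centres, r = 4) {
    st <- blank_stack(ny = 48, nx = 48, nz = 4, nuc = TRUE)
    for (cc in centres) {
      vox <- disc_voxels(cc[1], cc[2], r, z = 2)
      st$voxels[cbind(vox[, "y"] + 1, vox[, "x"] + 1, vox[, "z"] + 1, 3)] <- 170
    }
    st
  }
  roi <- rect_roi(x1 = 47, y1 = 47, z_bottom = 3)
  one <- count_nuclei(mk_nuc_stack(list(c(24, 24))), roi)
  expect_equal(one$n_nuclei, 1)
  expect_false(one$giant)
  four <- count_nuclei(mk_nuc_stack(list(c(10, 10), c(36, 10),
                                         c(10, 36), c(36, 36))), roi)
  expect_equal(four$n_nuclei, 4)
  expect_true(four$giant)
  # missing channel: skipped with a warning, not an error
  expect_warning(r <- count_nuclei(blank_stack(), roi), "NUC")
  expect_true(is.na(r$n_nuclei))
})

test_that("three identical groups give F ~ 0, p ~ 1, all pairs ns", {
  y <- rep(c(1, 2, 3, 4, 5, 6), 3) # same values in every group
  g <- rep(c("d1", "d7", "d30"), each = 6)
  r <- rm_anova_tukey(y, g)
  expect_lt(r$statistic, 1e-10)
  expect_gt(r$p_value, 0.999)
  expect_true(all(r$pairwise$code == "ns"))
})

test_that("a large separation yields **** on all pairs", {
  set.seed(4)
  y <- c(rnorm(10, 0, 1), rnorm(10, 10, 1))
  g <- rep(c("a", "b"), each = 10)
  r <- rm_anova_tukey(y, g)
  expect_true(all(r$pairwise$p_value < 1e-4))
  expect_true(all(r$pairwise$code == "****"))
  expect_lte(perm_anova_p(y, g, 2e4), 1e-3) # oracle agrees it is extreme
})

test_that("ANOVA p agrees with the label-permutation oracle", {
  set.seed(6)
  y <- c(rnorm(6, 0, 1), rnorm(6, 1.2, 1)) # moderate effect, n = 12
  g <- rep(c("a", "b"), each = 6)
  r <- rm_anova_tukey(y, g)
  p_perm <- perm_anova_p(y, g, 1e5)
  expect_lt(abs(r$p_value - p_perm), 0.02)
})

test_that("the RM design uses within-subject error and symmetric Tukey", {
  set.seed(7)
  subj_eff <- rnorm(8, 0, 5) # large between-subject spread
  y <- c(subj_eff + rnorm(8, 0, 0.3), subj_eff + 1 + rnorm(8, 0, 0.3),
         subj_eff + 2 + rnorm(8, 0, 0.3))
  lev <- rep(c("d1", "d7", "d30"), each = 8)
  subj <- rep(paste0("s", 1:8), 3)
  r <- rm_anova_tukey(y, lev, subj)
  expect_match(r$test, "RM")
  expect_lt(r$p_value, 1e-4) # within-subject error makes this obvious
  # ordinary ANOVA drowns the effect in subject variance
  r_plain <- rm_anova_tukey(y, lev)
  expect_gt(r_plain$p_value, r$p_value)
  # pairwise table covers all unordered pairs once
  expect_equal(nrow(r$pairwise), 3)
  expect_false(any(duplicated(r$pairwise$comparison)))
  # falls back (with a warning) when subjects are not shared
  expect_warning(rm_anova_tukey(y, lev, rep(1:24)), "falling back")
})

test_that("paired t-test matches the closed form and the sign-flip oracle", {
  set.seed(8)
  b <- rnorm(10, 0, 1)
  a <- b + rnorm(10, 1, 0.1) # differences ~ N(1, 0.1)
  r <- paired_ttest(a, b)
  d <- a - b
  t_closed <- mean(d) / (sd(d) / sqrt(10))
  expect_equal(r$statistic, t_closed, tolerance = 1e-12)
  expect_lt(r$p_value, 1e-4)
  expect_equal(r$code, "****")
  expect_lte(signflip_p(d), 2^-9) # oracle: all mass at the extreme

  # moderate effect: two-sided parametric p tracks the exact flip oracle
  set.seed(9)
  d2 <- rnorm(12, 0.6, 1)
  r2 <- paired_ttest(d2 + 5, rep(5, 12))
  expect_lt(abs(r2$p_value - signflip_p(d2)), 0.02)

  # swapping the series flips t, p unchanged
  r3 <- paired_ttest(b, a)
  expect_equal(r3$statistic, -r$statistic)
  expect_equal(r3$p_value, r$p_value)

  # degenerate cases
  same <- paired_ttest(1:5, 1:5)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_equal(same$code, "ns")
  degen <- paired_ttest(2:6, 1:5)
  expect_true(degen$degenerate)
  expect_equal(degen$p_value, 0)
})

test_that("the published-table audit passes every consistent row", {
  rows <- published_summary_rows()
  audited <- audit_table_consistency(rows)
  expect_true(all(audited$matches[audited$consistent]))
  expect_false(any(audited$matches[!audited$consistent]))
  expect_equal(sum(audited$consistent), 21)
})
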