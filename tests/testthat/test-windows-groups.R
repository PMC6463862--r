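test_that("sliding windows tile a 2.5 kb promoter into 24 windows", {
  sim <- simulate_coalescent_snps(10, 2500, 0.005, seed = 2)
  prof <- sliding_window_diversity(sim$alignment)
  expect_identical(nrow(prof), 24L)
  expect_identical(prof$start_offset, seq(-2500L, -200L, by = 100L))
  expect_identical(prof$end_offset[1L], -2301L)
  # each window's pi matches a direct computation on its columns
  w <- 7L
  direct <- nucleotide_diversity(
    aln_slice(sim$alignment, prof$start_col[w]:prof$end_col[w]))$pi_site
  expect_equal(prof$pi_site[w], direct)
})

test_that("a single full-length window equals whole-region diversity", {
  sim <- simulate_coalescent_snps(8, 600, 0.01, seed = 3)
  prof <- sliding_window_diversity(sim$alignment, window = 600L, step = 100L)
  expect_identical(nrow(prof), 1L)
  expect_equal(prof$pi_site, nucleotide_diversity(sim$alignment)$pi_site)
  expect_error(sliding_window_diversity(sim$alignment, window = 601L), "window")
})

test_that("window count formula and non-overlapping decomposition hold", {
  for (L in c(400L, 1000L, 2500L)) {
    sim <- simulate_coalescent_snps(6, L, 0.01, seed = L)
    for (w in c(100L, 200L)) {
      for (s in c(50L, 100L, w)) {
        prof <- sliding_window_diversity(sim$alignment, window = w, step = s)
        expect_identical(nrow(prof), (L - w) %/% s + 1L)
      }
    }
    # step == window partitions the region: length-weighted window mean
    # equals whole-region pi when windows cover the region exactly
    w <- 100L
    prof <- sliding_window_diversity(sim$alignment, window = w, step = w)
    expect_equal(mean(prof$pi_site),
                 nucleotide_diversity(sim$alignment)$pi_site)
  }
})

test_that("diversity confined to a band shows up only in covering windows", {
  m <- matrix("A", nrow = 6L, ncol = 1000L)
  hot <- 401:500
  set.seed(1)
  for (p in hot) m[sample(6L, 3L), p] <- "G"
  prof <- sliding_window_diversity(haplotype_alignment(m),
                                   window = 100L, step = 100L)
  overlaps <- prof$start_col <= max(hot) & prof$end_col >= min(hot)
  expect_true(all(prof$pi_site[overlaps] > 0))
  expect_true(all(prof$pi_site[!overlaps] == 0))
})

test_that("latitude bins are left-closed, right-open, last bin closed", {
  md <- accession_metadata(data.frame(
    accession = c("a", "b", "c", "d", "e", "f"),
    latitude = c(44.9, 45.0, 39, 60.0, 50.0, 41),
    longitude = 0))
  g <- assign_latitude_groups(md)
  expect_identical(g$group, c("40-45", "45-50", NA, "50-60", "50-60", "40-45"))
})

test_that("expression groups split RPKM at the stated boundaries", {
  x <- c(a = 100, b = 137, c = 480, d = 30, e = 169.9, f = 170, g = 500)
  g <- assign_expression_groups(x)
  expect_identical(g$group,
                   c("low", "medium", "high", NA, "medium", "high", NA))
})

test_that("rank-sum test is exact where enumeration is feasible", {
  # degenerate: identical samples
  expect_equal(wilcoxon_rank_sum(c(1, 1, 1), c(1, 1))$p, 1)
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3))$p, 1)

  # the classic fully-separated 3 vs 3 case, one-sided
  r <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6), alternative = "less")
  expect_equal(r$p, 1 / 20)
  expect_equal(r$U, 0)

  # exact agreement with full enumeration over all sizes nx + ny <= 10
  set.seed(31)
  for (nx in 1:8) {
    for (ny in 1:(10 - nx)) {
      if (ny < 1) next
      for (rep in 1:2) {
        x <- no_tie_sample(nx); y <- no_tie_sample(ny)
        for (alt in c("two.sided", "less", "greater")) {
          expect_equal(wilcoxon_rank_sum(x, y, alt)$p,
                       enumerate_wilcoxon_p(x, y, alt),
                       tolerance = 1e-12,
                       label = sprintf("nx=%d ny=%d alt=%s", nx, ny, alt))
        }
      }
    }
  }
})

test_that("tied samples use the corrected normal approximation", {
  x <- c(1, 2, 2, 3, 4, 5); y <- c(2, 3, 3, 4, 6, 7)
  r <- wilcoxon_rank_sum(x, y)
  ref <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = TRUE))
  expect_equal(r$p, ref$p.value)
  # and stays in the same ballpark as the full permutation distribution
  expect_equal(r$p, enumerate_wilcoxon_p(x, y), tolerance = 0.06)
})

test_that("group comparisons report means and rank-sum p-values", {
  set.seed(11)
  v <- c(rnorm(20, 10), rnorm(20, 10))
  g <- rep(c("a", "b"), each = 20L)
  r <- group_mean_comparison(v, g)
  expect_equal(r$summary$mean[r$summary$group == "a"], mean(v[g == "a"]))
  expect_equal(r$summary$median[r$summary$group == "b"], median(v[g == "b"]))
  # identical groups: p = 1
  ri <- group_mean_comparison(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3L))
  expect_equal(ri$pairwise$p, 1)
  # well-separated log-normal groups: tiny p
  vs <- c(exp(rnorm(40, log(100), 0.3)), exp(rnorm(40, log(400), 0.3)))
  rs <- group_mean_comparison(vs, rep(c("lo", "hi"), each = 40L))
  expect_lt(rs$pairwise$p, 1e-6)
  expect_error(group_mean_comparison(1:5, rep("a", 5)), "2 groups")
})

test_that("window comparison flags a planted high-diversity band", {
  grp <- make_band_groups(n_acc = 40L, seed = 77L)
  res <- compare_window_profiles(grp, focal = "focal", seed = 1L,
                                 n_resample = 60L)
  band <- res$start_offset >= -1600L & (res$start_offset + 199L) <= -500L
  expect_true(all(res$significant[band]))
  # backgrounds are identical between the groups: no flags off the band
  off <- res$start_offset + 199L < -1700L | res$start_offset > -400L
  expect_false(any(res$significant[off]))
})

test_that("window comparison degenerate inputs behave", {
  sim <- simulate_coalescent_snps(12, 800, 0.01, seed = 41)
  same <- list(g1 = sim$alignment, g2 = sim$alignment)
  res <- compare_window_profiles(same, focal = "g1", seed = 2L,
                                 n_resample = 30L)
  expect_false(any(res$significant))
  expect_error(compare_window_profiles(list(g1 = sim$alignment), "g1"),
               "two groups")
  tiny <- list(g1 = sim$alignment, g2 = aln_subset(sim$alignment, 1L))
  expect_warning(expect_error(
    compare_window_profiles(tiny, "g1", n_resample = 10L), "too few"),
    "< 2 accessions")
})

test_that("band mode compares whole-band window profiles between groups", {
  grp <- make_band_groups(n_acc = 30L, seed = 5L)
  res <- compare_window_profiles(grp, focal = "focal", mode = "windows",
                                 band = c(-1600L, -500L),
                                 alternative = "greater")
  expect_identical(res$n_windows, 10L)
  expect_true(res$significant)
})
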