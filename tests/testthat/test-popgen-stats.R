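# the hand-checkable 4-haplotype fixture: three segregating sites with
# allele splits (1,3), (2,2), (3,1)
fix4 <- haplotype_alignment(c("AAA", "AAC", "ACC", "GCC"),
                            accessions = paste0("h", 1:4))

test_that("segregating sites counts columns with >= 2 non-missing alleles", {
  expect_identical(segregating_sites(haplotype_alignment(c("ACGT", "ACGT"))), 0L)
  expect_identical(segregating_sites(fix4), 3L)
  # N does not make a column segregating, nor does it hide real variation
  aln <- haplotype_alignment(c("AN", "NA", "AC", "AN"))
  expect_identical(segregating_sites(aln), 1L)
  expect_error(segregating_sites(haplotype_alignment("ACGT")), "n >= 2")
})

test_that("nucleotide diversity matches hand counts and brute force", {
  two <- haplotype_alignment(c("AAAAAAAAAA", "AACAACAAAA"))
  nd <- nucleotide_diversity(two)
  expect_equal(nd$pi_locus, 2)
  expect_equal(nd$pi_site, 0.2)

  expect_equal(nucleotide_diversity(fix4)$pi_locus, 10 / 6)
  expect_equal(nucleotide_diversity(
    haplotype_alignment(c("AC", "AC", "AC")))$pi_locus, 0)

  # oracle equivalence on random small alignments, with missing data
  set.seed(7)
  for (i in 1:25) {
    n <- sample(2:5, 1); L <- sample(2:8, 1)
    m <- matrix(sample(c("A", "C", "G", "T", "N"), n * L, replace = TRUE,
                       prob = c(rep(0.22, 4), 0.12)), n, L)
    aln <- haplotype_alignment(m)
    expect_equal(nucleotide_diversity(aln)$pi_locus, brute_force_pi(aln))
  }
})

test_that("Watterson's theta follows S / a1", {
  expect_equal(watterson_theta(0, 10, 100)$theta_locus, 0)
  expect_equal(watterson_theta(5, 2, 100)$theta_locus, 5)   # a1 = 1
  th <- watterson_theta(3, 4, 3)
  expect_equal(th$theta_locus, 3 / (1 + 1 / 2 + 1 / 3))
  expect_equal(th$theta_site, th$theta_locus / 3)
})

test_that("Tajima's D reproduces an independent hand computation", {
  # constants recomputed here from their definitions, independently
  n <- 4; S <- 3; pi <- 10 / 6
  a1 <- 1 + 1 / 2 + 1 / 3; a2 <- 1 + 1 / 4 + 1 / 9
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  d_expected <- (pi - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))

  d <- tajimas_d(fix4)
  expect_true(d$defined)
  expect_equal(d$D, d_expected)
  expect_equal(d$D, 0.168, tolerance = 0.003)

  # a balanced mix of singleton and 2:2 sites with pi = S/a1 exactly:
  # zero numerator, D = 0
  aln0 <- make_pi_equals_theta_aln()
  expect_equal(nucleotide_diversity(aln0)$pi_locus,
               watterson_theta(segregating_sites(aln0), 4, 11)$theta_locus)
  expect_equal(tajimas_d(aln0)$D, 0, tolerance = 1e-9)

  # undefined when no variation
  expect_false(tajimas_d(haplotype_alignment(c("AA", "AA", "AA")))$defined)
  expect_error(tajimas_d(haplotype_alignment(c("AA", "AA"))), "n >= 3")
})

test_that("D's beta-approximation bounds agree with numeric integration", {
  for (n in c(6L, 20L, 100L)) {
    k <- tajima_constants(n)
    dmin <- (2 / n - 1 / k$a1) / sqrt(k$e2)
    dmax <- (n / (2 * (n - 1)) - 1 / k$a1) / sqrt(k$e2)
    A <- -(1 + dmin * dmax) * dmax / (dmax - dmin)
    B <- (1 + dmin * dmax) * dmin / (dmax - dmin)
    dens <- function(D) {
      (dmax - D)^(A - 1) * (D - dmin)^(B - 1) /
        (beta(A, B) * (dmax - dmin)^(A + B - 1))
    }
    # independent quantile: numeric integration of the density
    grid <- seq(dmin + 1e-9, dmax - 1e-9, length.out = 200001L)
    cdf <- cumsum(dens(grid)) * diff(grid[1:2])
    q_num <- function(p) grid[which.min(abs(cdf - p))]
    b <- tajima_d_bounds(n, alpha = 0.05)
    expect_equal(b[["lower"]], q_num(0.025), tolerance = 1e-3)
    expect_equal(b[["upper"]], q_num(0.975), tolerance = 1e-3)
  }
})

test_that("Tajima significance is an interval test with sane behaviour", {
  for (n in c(6L, 20L, 774L)) {
    expect_false(tajima_significance(0, n))
    expect_false(tajima_significance(0.9, 774L))
    expect_false(tajima_significance(-0.9, 774L))
  }
  b <- tajima_d_bounds(20L)
  expect_true(tajima_significance(b[["lower"]] - 0.01, 20L))
  expect_true(tajima_significance(b[["upper"]] + 0.01, 20L))
  # monotonicity: larger |D|, same sign, stays significant
  expect_true(tajima_significance(b[["lower"]] - 1, 20L))
  expect_error(tajima_significance(0, 3L), "n < 4")
})

test_that("MAF spectrum counts minor alleles, singletons and classes", {
  roster <- sprintf("a%03d", 1:20)
  df <- data.frame(
    accession = c("a001",                       # singleton
                  "a001", "a002",               # doubleton
                  roster[1:19]),                # 19/20 -> minor = ref = 1
    chrom = "chr1",
    pos = c(10L, 20L, 20L, rep(30L, 19L)),
    ref = "G", alt = "A", qual = 40)
  st <- snp_table(df, roster = roster)
  sp <- maf_spectrum(st, classes = c("chr1:10" = "nonsynonymous",
                                     "chr1:20" = "synonymous",
                                     "chr1:30" = "nonsynonymous"))
  expect_identical(sp$per_snp$minor_count, c(1L, 2L, 1L))
  expect_true(sp$per_snp$singleton[1L])
  expect_true(sp$per_snp$singleton[3L])   # minor allele is the reference
  expect_equal(unname(sp$singleton_fraction[["nonsynonymous"]]), 1)
  expect_equal(unname(sp$singleton_fraction[["synonymous"]]), 0)
  expect_equal(unname(sp$singleton_fraction[["all"]]), 2 / 3)
  expect_identical(sum(sp$histogram), nrow(sp$per_snp))

  # the 4-haplotype fixture: minor counts (1,2,1) -> singleton fraction 2/3
  df4 <- data.frame(accession = c("h4", "h3", "h4", "h2", "h3", "h4"),
                    chrom = "c", pos = c(1L, 2L, 2L, 3L, 3L, 3L),
                    ref = "A", alt = "C", qual = 40)
  sp4 <- maf_spectrum(snp_table(df4, roster = paste0("h", 1:4)))
  expect_identical(sp4$per_snp$minor_count, c(1L, 2L, 1L))
  expect_equal(unname(sp4$singleton_fraction[["all"]]), 2 / 3)

  # monomorphic rows are excluded and counted
  dfm <- data.frame(accession = roster, chrom = "chr1", pos = 50L,
                    ref = "T", alt = "C", qual = 40)
  spm <- maf_spectrum(snp_table(dfm, roster = roster))
  expect_identical(nrow(spm$per_snp), 0L)
  expect_identical(spm$n_monomorphic_excluded, 1L)
})

test_that("coding SNPs are classified against the genetic code", {
  cds <- "ATGCTGTGGTAA"  # M L W *
  fm <- setNames(1:12, paste0("chr1:", 101:112))
  snps <- data.frame(chrom = "chr1",
                     pos = c(106L, 103L, 109L),
                     ref = c("G", "G", "G"),
                     alt = c("A", "A", "A"))
  cl <- classify_coding_snps(snps, cds, fm)
  # CTG -> CTA : Leu -> Leu
  expect_identical(cl$class[1L], "synonymous")
  # ATG -> ATA : Met -> Ile
  expect_identical(cl$class[2L], "nonsynonymous")
  # TGG -> TGA : Trp -> stop, nonsense
  expect_identical(cl$class[3L], "nonsynonymous")
  expect_true(cl$nonsense[3L])
  expect_false(any(cl$nonsense[1:2]))
  expect_error(classify_coding_snps(data.frame(chrom = "chr1", pos = 999L,
                                               ref = "A", alt = "C"),
                                    cds, fm), "frame map")
})

test_that("pi and D are invariant under row permutation; sign law holds", {
  set.seed(9)
  sim <- simulate_coalescent_snps(12, 200, 0.03, seed = 13)
  aln <- sim$alignment
  perm <- aln_subset(aln, sample(aln_n(aln)))
  expect_equal(nucleotide_diversity(perm)$pi_locus,
               nucleotide_diversity(aln)$pi_locus)
  expect_equal(tajimas_d(perm)$D, tajimas_d(aln)$D)
  # sign of D equals sign of pi - theta
  s <- polymorphism_summary(aln)
  expect_identical(sign(s$tajima_d), sign(s$pi_locus - s$theta_locus))
  expect_lte(s$pi_site, 1)
})

test_that("estimators are calibrated on neutral simulations (small run)", {
  reps <- 150L; n <- 20L; L <- 500L; theta <- 0.02
  res <- vapply(seq_len(reps), function(i) {
    s <- polymorphism_summary(
      simulate_coalescent_snps(n, L, theta, seed = 5000L + i)$alignment)
    c(s$pi_site, s$theta_site)
  }, numeric(2L))
  se_pi <- sd(res[1L, ]) / sqrt(reps)
  se_th <- sd(res[2L, ]) / sqrt(reps)
  expect_lt(abs(mean(res[1L, ]) - theta), 3 * se_pi)
  expect_lt(abs(mean(res[2L, ]) - theta), 3 * se_th)
})
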