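# Independent oracles used across the suite. These deliberately use naive
# algorithms (double loops, exhaustive enumeration, series expansions) so
# they share no code with the implementation paths they check.

# pi by explicit double loop over all sequence pairs, pairwise deletion
brute_force_pi <- function(aln) {
  m <- aln$seq
  n <- nrow(m)
  tot <- 0
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- m[i, ] != "N" & m[j, ] != "N"
      tot <- tot + sum(m[i, ok] != m[j, ok])
    }
  }
  tot / choose(n, 2)
}

# exact Mann-Whitney p by enumerating all C(n, nx) group labelings
enumerate_wilcoxon_p <- function(x, y, alternative = "two.sided") {
  all_v <- c(x, y)
  nx <- length(x)
  r <- rank(all_v)
  u_of <- function(idx) sum(r[idx]) - nx * (nx + 1) / 2
  u_obs <- u_of(seq_len(nx))
  combos <- utils::combn(length(all_v), nx)
  us <- apply(combos, 2L, u_of)
  p_le <- mean(us <= u_obs)
  p_ge <- mean(us >= u_obs)
  switch(alternative,
         less = p_le,
         greater = p_ge,
         two.sided = min(1, 2 * min(p_le, p_ge)))
}

# optimal global alignment score by exhaustive recursion (tiny inputs only)
brute_force_nw_score <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  A <- strsplit(a, "")[[1L]]
  B <- strsplit(b, "")[[1L]]
  rec <- function(i, j) {
    if (i == 0L && j == 0L) return(0)
    best <- -Inf
    if (i > 0L && j > 0L) {
      best <- max(best, rec(i - 1L, j - 1L) +
                    (if (A[i] == B[j]) match else mismatch))
    }
    if (i > 0L) best <- max(best, rec(i - 1L, j) + gap)
    if (j > 0L) best <- max(best, rec(i, j - 1L) + gap)
    best
  }
  rec(length(A), length(B))
}

# matrix exponential by plain Taylor series with scaling and squaring
series_expm <- function(M, t, n_terms = 60L) {
  A <- M * t
  s <- max(0L, ceiling(log2(max(1, max(abs(A))))))
  A <- A / 2^s
  P <- diag(nrow(A))
  term <- diag(nrow(A))
  for (k in seq_len(n_terms)) {
    term <- term %*% A / k
    P <- P + term
  }
  for (k in seq_len(s)) P <- P %*% P
  P
}

# an n = 4 alignment with pi exactly equal to Watterson's theta:
# 8 singleton-pattern sites (3 discordant pairs each) and 3 balanced 2:2
# sites (4 each) give pi = 36/6 = 6 = 11/a1(4), so Tajima's D = 0
make_pi_equals_theta_aln <- function() {
  m <- matrix("A", 4L, 11L)
  for (s in 1:8) m[(s - 1L) %% 4L + 1L, s] <- "C"
  m[1:2, 9:11] <- "C"
  haplotype_alignment(m)
}

# a random no-tie numeric sample
no_tie_sample <- function(n) sample(seq_len(100L), n) + runif(n, -0.2, 0.2)

# two-group window fixture: identical backgrounds, elevated diversity in the
# band for the focal group only (band given as offsets, e.g. -1600..-500)
make_band_groups <- function(n_acc = 40L, L = 2500L, theta_bg = 0.002,
                             theta_band = 0.03, band = c(-1600, -500),
                             seed = 1L) {
  cols <- (band[1L] + L + 1L):(band[2L] + L + 1L)
  bg <- simulate_coalescent_snps(n_acc, L, theta_bg, seed = seed)$alignment
  focal_seq <- other_seq <- bg$seq
  hot <- simulate_coalescent_snps(n_acc, length(cols), theta_band,
                                  seed = seed + 1000L)$alignment
  cold <- simulate_coalescent_snps(n_acc, length(cols), theta_bg,
                                   seed = seed + 2000L)$alignment
  focal_seq[, cols] <- hot$seq
  other_seq[, cols] <- cold$seq
  list(focal = haplotype_alignment(focal_seq, region_id = "focal"),
       other = haplotype_alignment(other_seq, region_id = "other"))
}
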