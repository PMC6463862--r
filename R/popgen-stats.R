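# Diversity statistics per gene region: segregating sites, nucleotide
# diversity, Watterson's theta, Tajima's D (with its beta-approximation
# significance bounds), minor-allele-frequency spectra and synonymous /
# nonsynonymous SNP classification.

site_allele_counts <- function(aln) {
  # counts of A/C/G/T per column; N and '-' treated as missing
  m <- aln$seq
  vapply(c("A", "C", "G", "T"),
         function(b) .colSums(m == b, nrow(m), ncol(m)),
         numeric(ncol(m)))
}

#' Number of segregating sites
#'
#' A column is segregating when at least two distinct non-missing (non-N)
#' alleles are present; missing data do not disqualify a column.
#'
#' @param aln A [haplotype_alignment()] with at least two sequences.
#' @return Integer count of segregating columns.
#' @export
segregating_sites <- function(aln) {
  if (aln_n(aln) < 2L) stop("segregating_sites: need n >= 2 sequences")
  cnt <- site_allele_counts(aln)
  if (ncol(aln$seq) == 0L) return(0L)
  sum(rowSums(cnt > 0) >= 2L)
}

#' Nucleotide diversity (pi)
#'
#' Mean number of pairwise differences between sequences. For each pair,
#' differences are counted over sites where both sequences are non-missing
#' (pairwise deletion), then averaged over all `choose(n, 2)` pairs.
#'
#' @param aln A [haplotype_alignment()] with at least two sequences.
#' @return List with `pi_locus` (mean pairwise differences per pair) and
#'   `pi_site` (`pi_locus / L`).
#' @export
nucleotide_diversity <- function(aln) {
  n <- aln_n(aln)
  if (n < 2L) stop("nucleotide_diversity: need n >= 2 sequences")
  L <- aln_length(aln)
  if (L == 0L) stop("nucleotide_diversity: zero-length alignment")
  cnt <- site_allele_counts(aln)
  m <- rowSums(cnt)                      # non-missing per site
  # discordant pairs per site = C(m,2) - sum_a C(m_a,2)
  disc <- m * (m - 1) / 2 - rowSums(cnt * (cnt - 1) / 2)
  pi_locus <- sum(disc) / (n * (n - 1) / 2)
  list(pi_locus = pi_locus, pi_site = pi_locus / L)
}

#' Watterson's theta
#'
#' `theta_locus = S / a1(n)` with `a1 = sum(1/i, i = 1..n-1)`; an estimator of
#' the population mutation rate from the count of segregating sites.
#'
#' @param S Number of segregating sites.
#' @param n Sample size (number of sequences), `n >= 2`.
#' @param L Alignment length in sites.
#' @return List with `theta_locus` and `theta_site`.
#' @export
watterson_theta <- function(S, n, L) {
  if (n < 2L) stop("watterson_theta: need n >= 2")
  a1 <- sum(1 / seq_len(n - 1L))
  theta_locus <- S / a1
  list(theta_locus = theta_locus, theta_site = theta_locus / L)
}

#' Constants of Tajima's D
#'
#' The classical `a1, a2, b1, b2, c1, c2, e1, e2` coefficients, functions of
#' the sample size only.
#'
#' @param n Sample size, `n >= 2` (`n >= 3` for the full D statistic).
#' @return Named list of the eight constants.
#' @export
tajima_constants <- function(n) {
  if (n < 2L) stop("tajima_constants: need n >= 2")
  i <- seq_len(n - 1L)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2, e1 = e1, e2 = e2)
}

#' Tajima's D
#'
#' `D = (pi_locus - S/a1) / sqrt(e1*S + e2*S*(S-1))`. Negative values arise
#' from an excess of rare variants (purifying selection or expansion);
#' values near zero are consistent with neutrality at equilibrium. D is
#' undefined when there are no segregating sites.
#'
#' @param aln A [haplotype_alignment()] with at least three sequences.
#' @return List with `D` (`NA` when undefined) and `defined` (logical).
#' @export
tajimas_d <- function(aln) {
  if (aln_n(aln) < 3L) stop("tajimas_d: need n >= 3 sequences")
  S <- segregating_sites(aln)
  if (S == 0L) return(list(D = NA_real_, defined = FALSE))
  k <- tajima_constants(aln_n(aln))
  pi_locus <- nucleotide_diversity(aln)$pi_locus
  D <- (pi_locus - S / k$a1) / sqrt(k$e1 * S + k$e2 * S * (S - 1))
  list(D = D, defined = TRUE)
}

#' Neutral confidence bounds for Tajima's D (beta approximation)
#'
#' Under neutrality D is approximately a generalised beta variable with mean
#' 0 and variance 1 on the interval `[Dmin, Dmax]` fixed by the sample size:
#' `Dmin = (2/n - 1/a1)/sqrt(e2)` (all-singleton extreme) and
#' `Dmax = (n/(2(n-1)) - 1/a1)/sqrt(e2)` (balanced-site extreme). The
#' two-sided `(1 - alpha)` interval is obtained from the beta quantiles.
#'
#' @param n Sample size, `n >= 4`.
#' @param alpha Two-sided significance level.
#' @return Numeric vector `c(lower, upper)`.
#' @export
tajima_d_bounds <- function(n, alpha = 0.05) {
  if (n < 4L) stop("tajima_d_bounds: unsupported for n < 4")
  k <- tajima_constants(n)
  dmin <- (2 / n - 1 / k$a1) / sqrt(k$e2)
  dmax <- (n / (2 * (n - 1)) - 1 / k$a1) / sqrt(k$e2)
  # generalised beta on [dmin, dmax] with mean 0, variance 1:
  # density prop. to (dmax - D)^(A-1) (D - dmin)^(B-1)
  A <- -(1 + dmin * dmax) * dmax / (dmax - dmin)
  B <- (1 + dmin * dmax) * dmin / (dmax - dmin)
  q <- function(p) dmin + (dmax - dmin) * qbeta(p, shape1 = B, shape2 = A)
  c(lower = q(alpha / 2), upper = q(1 - alpha / 2))
}

#' Significance of an observed Tajima's D
#'
#' `TRUE` when D falls outside the two-sided `(1 - alpha)` neutral interval
#' from [tajima_d_bounds()].
#'
#' @param D Observed Tajima's D.
#' @param n Sample size, `n >= 4`.
#' @param alpha Two-sided significance level.
#' @return Logical.
#' @export
tajima_significance <- function(D, n, alpha = 0.05) {
  if (is.na(D)) stop("tajima_significance: D is undefined")
  b <- tajima_d_bounds(n, alpha)
  D < b[["lower"]] || D > b[["upper"]]
}

#' Summarise polymorphism for one region
#'
#' Bundles S, pi, Watterson's theta and Tajima's D (with its significance
#' call) for one region alignment.
#'
#' @param aln A [haplotype_alignment()].
#' @param alpha Significance level for the Tajima's D call.
#' @return A one-row data.frame (`region`, `n`, `L`, `S`, `pi_locus`,
#'   `pi_site`, `theta_locus`, `theta_site`, `tajima_d`, `d_defined`,
#'   `d_significant`).
#' @export
polymorphism_summary <- function(aln, alpha = 0.05) {
  n <- aln_n(aln); L <- aln_length(aln)
  S <- segregating_sites(aln)
  pi <- nucleotide_diversity(aln)
  th <- watterson_theta(S, n, L)
  d <- if (n >= 3L) tajimas_d(aln) else list(D = NA_real_, defined = FALSE)
  sig <- if (d$defined && n >= 4L) tajima_significance(d$D, n, alpha) else NA
  data.frame(region = aln$region_id, n = n, L = L, S = S,
             pi_locus = pi$pi_locus, pi_site = pi$pi_site,
             theta_locus = th$theta_locus, theta_site = th$theta_site,
             tajima_d = d$D, d_defined = d$defined, d_significant = sig,
             stringsAsFactors = FALSE)
}

#' Minor-allele-frequency spectrum
#'
#' For each SNP the minor-allele count is `min(alt count, n - alt count)`
#' under the reference-fill convention (accessions without a record carry
#' the reference allele). A singleton is a SNP whose minor-allele count is 1.
#' Sites that turn out monomorphic in the roster (alt count 0 or n) are
#' excluded and counted.
#'
#' @param snps A [snp_table()].
#' @param classes Optional named character vector mapping `"chrom:pos"` keys
#'   to functional classes (e.g. `"synonymous"`, `"nonsynonymous"`,
#'   `"noncoding"`); unmapped SNPs get class `"unclassified"`.
#' @param maf_breaks Breakpoints for the minor-allele-frequency histogram.
#' @return List with `per_snp` (data.frame: chrom, pos, alt_count,
#'   minor_count, maf, singleton, class), `histogram` (counts per MAF bin),
#'   `singleton_fraction` (named by class, plus `"all"`), and
#'   `n_monomorphic_excluded`.
#' @export
maf_spectrum <- function(snps, classes = NULL,
                         maf_breaks = seq(0, 0.5, by = 0.05)) {
  n <- length(snp_roster(snps))
  if (n < 2L) stop("maf_spectrum: roster must have >= 2 accessions")
  df <- as.data.frame(snps)
  key <- paste(df$chrom, df$pos, sep = ":")
  alt_count <- as.integer(table(key)[unique(key)])
  u <- !duplicated(key)
  per <- data.frame(chrom = df$chrom[u], pos = df$pos[u],
                    alt_count = alt_count, stringsAsFactors = FALSE)
  mono <- per$alt_count == 0L | per$alt_count >= n
  n_mono <- sum(mono)
  per <- per[!mono, , drop = FALSE]
  per$minor_count <- pmin(per$alt_count, n - per$alt_count)
  per$maf <- per$minor_count / n
  per$singleton <- per$minor_count == 1L
  pkey <- paste(per$chrom, per$pos, sep = ":")
  per$class <- if (is.null(classes)) rep("unclassified", nrow(per)) else {
    cl <- unname(classes[pkey]); cl[is.na(cl)] <- "unclassified"; cl
  }
  hist_counts <- table(cut(per$maf, breaks = maf_breaks, include.lowest = TRUE,
                           right = TRUE))
  sf <- tapply(per$singleton, per$class, mean)
  sf <- c(sf, all = mean(per$singleton))
  list(per_snp = per, histogram = hist_counts,
       singleton_fraction = sf, n_monomorphic_excluded = n_mono)
}

#' Classify coding SNPs as synonymous or nonsynonymous
#'
#' Each SNP's alternate allele is substituted into its reference codon and
#' the translations compared under the standard genetic code. Stop-gain and
#' stop-loss changes are classed nonsynonymous and flagged as nonsense.
#'
#' @param snps A [snp_table()] (or plain data.frame with `chrom`, `pos`,
#'   `ref`, `alt`); one classification per unique (chrom, pos, alt).
#' @param cds Coding sequence (character scalar, length divisible by 3),
#'   given 5'->3' on the coding strand.
#' @param frame_map Integer vector mapping chromosomal positions to CDS
#'   positions: `names(frame_map)` are `"chrom:pos"` keys, values are 1-based
#'   positions within `cds`. SNPs without an entry raise an error.
#' @return Data.frame with `chrom`, `pos`, `ref`, `alt`, `cds_pos`,
#'   `codon_ref`, `codon_alt`, `aa_ref`, `aa_alt`, `class`, `nonsense`.
#' @export
classify_coding_snps <- function(snps, cds, frame_map) {
  cds <- toupper(cds)
  if (nchar(cds) %% 3L != 0L) stop("classify_coding_snps: CDS length not divisible by 3")
  df <- unique(as.data.frame(snps)[, c("chrom", "pos", "ref", "alt")])
  key <- paste(df$chrom, df$pos, sep = ":")
  cpos <- unname(frame_map[key])
  if (any(is.na(cpos))) {
    stop("classify_coding_snps: SNP position(s) not in frame map: ",
         paste(key[is.na(cpos)], collapse = ", "))
  }
  cds_chars <- strsplit(cds, "", fixed = TRUE)[[1L]]
  code <- Biostrings::GENETIC_CODE
  out <- lapply(seq_len(nrow(df)), function(i) {
    p <- cpos[i]
    ci <- (p - 1L) %/% 3L            # codon index, 0-based
    off <- (p - 1L) %% 3L + 1L       # position within codon
    codon_ref <- paste(cds_chars[(ci * 3L + 1L):(ci * 3L + 3L)], collapse = "")
    if (substr(codon_ref, off, off) != df$ref[i]) {
      # strand-flipped SNPs must be complemented before classification
      stop("classify_coding_snps: ref allele ", df$ref[i], " at ", key[i],
           " does not match CDS base ", substr(codon_ref, off, off))
    }
    codon_alt <- codon_ref
    substr(codon_alt, off, off) <- df$alt[i]
    aa_ref <- unname(code[codon_ref]); aa_alt <- unname(code[codon_alt])
    data.frame(chrom = df$chrom[i], pos = df$pos[i], ref = df$ref[i],
               alt = df$alt[i], cds_pos = p, codon_ref = codon_ref,
               codon_alt = codon_alt, aa_ref = aa_ref, aa_alt = aa_alt,
               class = if (aa_ref == aa_alt) "synonymous" else "nonsynonymous",
               nonsense = (aa_ref != "*" & aa_alt == "*") |
                          (aa_ref == "*" & aa_alt != "*"),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
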