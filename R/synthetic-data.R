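# Generators that produce inputs with the statistical structure the analysis
# assumes, with known ground truth: coalescent SNP panels, diverged codon
# pairs, latitude-structured expression, and gene tables with prescribed
# spacing for the tandem-duplication rule.

with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

random_reference <- function(L) {
  paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
}

#' Simulate a SNP panel under the standard neutral coalescent
#'
#' Draws a Kingman coalescent genealogy for `n_accessions` haploid samples
#' (exponential waiting times with rate `k(k-1)/2`, random pair merges),
#' places mutations on branches as a Poisson process with total rate
#' `theta_site * region_length / 2` per unit coalescent time, and renders the
#' resulting haplotypes onto a random reference sequence under the
#' infinite-sites model (each mutation at a distinct uniformly drawn site;
#' site collisions are redrawn). Under this model the expected number of
#' segregating sites is `theta_site * L * a1(n)`.
#'
#' Phred qualities are drawn per SNP record: with probability `prob_pass` a
#' quality uniform on `qual_pass`, otherwise uniform on `qual_fail`. The
#' returned alignment contains the *true* haplotypes (all mutations,
#' regardless of quality); the SNP table is what a caller would feed to the
#' quality-filtered assembly.
#'
#' @param n_accessions Number of haploid samples, `>= 2`.
#' @param region_length Region length in bp.
#' @param theta_site Scaled mutation rate per site (`theta >= 0`).
#' @param seed Integer seed; the generator is bit-for-bit reproducible.
#' @param chrom,start Chromosomal placement of the simulated region.
#' @param prob_pass,qual_pass,qual_fail Quality model (defaults: 95% of
#'   records at Phred >= 25).
#' @return List with `snps` (a [snp_table()]), `alignment`
#'   (a [haplotype_alignment()]), `reference` (character scalar) and
#'   `truth` (list: `theta_site`, `n_mutations`, `seed`).
#' @export
simulate_coalescent_snps <- function(n_accessions, region_length, theta_site,
                                     seed = NULL, chrom = "chr1", start = 1L,
                                     prob_pass = 0.95, qual_pass = c(25, 60),
                                     qual_fail = c(0, 24.9)) {
  if (n_accessions < 2L) stop("simulate_coalescent_snps: need n >= 2")
  if (theta_site < 0) stop("simulate_coalescent_snps: theta must be >= 0")
  L <- as.integer(region_length)
  with_seed(seed, {
    acc <- sprintf("acc%03d", seq_len(n_accessions))
    ref <- random_reference(L)
    ref_chars <- strsplit(ref, "", fixed = TRUE)[[1L]]

    # genealogy: record one (leaf set, branch length) per non-root lineage
    active <- lapply(seq_len(n_accessions), function(i) i)
    birth <- rep(0, n_accessions)
    t <- 0
    branch_sets <- vector("list", 2L * (n_accessions - 1L))
    branch_len <- numeric(2L * (n_accessions - 1L))
    bi <- 0L
    while (length(active) > 1L) {
      k <- length(active)
      t <- t + rexp(1L, rate = k * (k - 1) / 2)
      pair <- sample.int(k, 2L)
      for (j in pair) {
        bi <- bi + 1L
        branch_sets[[bi]] <- active[[j]]
        branch_len[bi] <- t - birth[j]
      }
      merged <- c(active[[pair[1L]]], active[[pair[2L]]])
      active <- c(active[-pair], list(merged))
      birth <- c(birth[-pair], t)
    }
    total_len <- sum(branch_len)

    n_mut <- if (theta_site > 0) rpois(1L, theta_site * L / 2 * total_len) else 0L
    n_mut <- min(n_mut, L)  # infinite-sites needs distinct sites
    sites <- integer(0)
    if (n_mut > 0L) {
      sites <- sample.int(L, n_mut, replace = FALSE)
      on_branch <- sample.int(bi, n_mut, replace = TRUE,
                              prob = branch_len[seq_len(bi)])
    }

    aln <- matrix(rep(ref_chars, each = n_accessions), nrow = n_accessions)
    snp_rows <- vector("list", n_mut)
    for (m in seq_len(n_mut)) {
      s <- sites[m]
      carriers <- branch_sets[[on_branch[m]]]
      derived <- sample(setdiff(c("A", "C", "G", "T"), ref_chars[s]), 1L)
      aln[carriers, s] <- derived
      qual <- ifelse(runif(length(carriers)) < prob_pass,
                     runif(length(carriers), qual_pass[1L], qual_pass[2L]),
                     runif(length(carriers), qual_fail[1L], qual_fail[2L]))
      snp_rows[[m]] <- data.frame(
        accession = acc[carriers], chrom = chrom,
        pos = start + s - 1L, ref = ref_chars[s], alt = derived,
        qual = qual, stringsAsFactors = FALSE)
    }
    df <- if (n_mut) do.call(rbind, snp_rows) else
      data.frame(accession = character(), chrom = character(), pos = integer(),
                 ref = character(), alt = character(), qual = numeric())
    df <- df[order(df$pos, df$accession), , drop = FALSE]
    list(
      snps = snp_table(df, roster = acc),
      alignment = haplotype_alignment(aln, accessions = acc,
                                      region_id = "simulated",
                                      coords = start + seq_len(L) - 1L,
                                      chrom = chrom),
      reference = ref,
      truth = list(theta_site = theta_site, n_mutations = n_mut, seed = seed))
  })
}

#' Simulate a diverged codon-sequence pair
#'
#' The ancestor is drawn from the stationary codon frequencies; the
#' descendant evolves for time `t` under a GY94-style continuous-time process
#' (single-nucleotide changes only, transition factor `kappa`, nonsynonymous
#' factor `omega`) by sampling each codon from the transition matrix
#' `exp(Q t)`. The state space is the 61 sense codons of the universal code;
#' codons evolve independently.
#'
#' @param n_codons Number of codons, `>= 1`.
#' @param t Divergence time in expected substitutions per codon.
#' @param kappa Transition/transversion rate ratio, `> 0`.
#' @param omega dN/dS ratio, `>= 0`.
#' @param seed Integer seed.
#' @param codon_freqs Stationary frequencies over the 61 sense codons
#'   (default equal).
#' @return List with `seq_a`, `seq_b` (nucleotide strings, length
#'   `3 * n_codons`) and `truth` (list: `t`, `kappa`, `omega`, `seed`).
#' @export
simulate_codon_pair <- function(n_codons, t, kappa, omega, seed = NULL,
                                codon_freqs = NULL) {
  if (n_codons < 1L) stop("simulate_codon_pair: need n_codons >= 1")
  if (t < 0 || kappa <= 0 || omega < 0) {
    stop("simulate_codon_pair: invalid parameters")
  }
  cs <- codon_space()
  if (is.null(codon_freqs)) codon_freqs <- rep(1 / 61, 61L)
  if (length(codon_freqs) != 61L || abs(sum(codon_freqs) - 1) > 1e-8) {
    stop("simulate_codon_pair: codon_freqs must be 61 values summing to 1")
  }
  with_seed(seed, {
    anc <- sample.int(61L, n_codons, replace = TRUE, prob = codon_freqs)
    if (t == 0) {
      seq_a <- paste(cs$codons[anc], collapse = "")
      return(list(seq_a = seq_a, seq_b = seq_a,
                  truth = list(t = t, kappa = kappa, omega = omega, seed = seed)))
    }
    P <- codon_transition_matrix(t, kappa, omega, codon_freqs)
    des <- vapply(anc, function(i) sample.int(61L, 1L, prob = P[i, ]), integer(1L))
    list(seq_a = paste(cs$codons[anc], collapse = ""),
         seq_b = paste(cs$codons[des], collapse = ""),
         truth = list(t = t, kappa = kappa, omega = omega, seed = seed))
  })
}

#' Simulate latitude-structured expression values
#'
#' RPKM values are log-normal around group-specific means: for an accession
#' in group g, `RPKM = exp(log(group_means[g]) + rnorm(1, 0, noise_sd))`,
#' so `noise_sd = 0` returns each group's mean exactly.
#'
#' @param metadata Data.frame with columns `accession` and `group`; every
#'   accession must carry a group label present in `group_means`.
#' @param group_means Named positive vector of group mean RPKM.
#' @param noise_sd Log-scale standard deviation, `>= 0`.
#' @param seed Integer seed.
#' @param gene_id Row label of the output matrix.
#' @return An [expression_matrix()] with one row (`gene_id`) and one column
#'   per accession.
#' @export
simulate_expression <- function(metadata, group_means, noise_sd, seed = NULL,
                                gene_id = "gene1") {
  if (noise_sd < 0) stop("simulate_expression: noise_sd must be >= 0")
  if (!all(c("accession", "group") %in% names(metadata))) {
    stop("simulate_expression: metadata needs accession and group columns")
  }
  g <- as.character(metadata$group)
  if (any(is.na(g)) || !all(g %in% names(group_means))) {
    stop("simulate_expression: every accession needs a group in group_means")
  }
  with_seed(seed, {
    mu <- log(group_means[g])
    vals <- exp(mu + rnorm(nrow(metadata), 0, noise_sd))
    m <- matrix(vals, nrow = 1L,
                dimnames = list(gene_id, as.character(metadata$accession)))
    expression_matrix(m)
  })
}

#' Generate a gene table with prescribed spacing
#'
#' Lays out `n_genes` single-exon gene models left-to-right on one
#' chromosome, honouring the given intergenic gaps exactly. Used to build
#' fixtures for the tandem-duplication rule with known intervening-gene
#' counts and boundary distances.
#'
#' @param n_genes Number of genes.
#' @param family_member_indices Indices (1-based) of the genes that belong to
#'   the family of interest.
#' @param gaps Integer vector of length `n_genes - 1`: boundary distance
#'   `start(gene i+1) - end(gene i)`, the same quantity the
#'   tandem-duplication rule thresholds. Must be `>= 1` (no overlaps).
#' @param gene_length Length of every gene (scalar or vector).
#' @param seed Unused placeholder kept for API uniformity; the layout is
#'   deterministic.
#' @param chrom Chromosome name.
#' @param start Start of the first gene.
#' @return List with `genes` (list of [gene_model()]) and `family_ids`
#'   (character vector of family member gene ids).
#' @export
generate_gene_table <- function(n_genes, family_member_indices, gaps,
                                gene_length = 1000L, seed = NULL,
                                chrom = "chr1", start = 1001L) {
  if (length(gaps) != n_genes - 1L) {
    stop("generate_gene_table: need n_genes - 1 gaps")
  }
  if (any(gaps < 1L)) stop("generate_gene_table: overlapping placements (gap < 1)")
  len <- rep_len(as.integer(gene_length), n_genes)
  starts <- integer(n_genes); ends <- integer(n_genes)
  pos <- as.integer(start)
  for (i in seq_len(n_genes)) {
    starts[i] <- pos
    ends[i] <- pos + len[i] - 1L
    if (i < n_genes) pos <- ends[i] + as.integer(gaps[i])
  }
  ids <- sprintf("gene%03d", seq_len(n_genes))
  genes <- lapply(seq_len(n_genes), function(i) {
    gene_model(ids[i], chrom, "+", starts[i], ends[i],
               exons = data.frame(start = starts[i], end = ends[i]))
  })
  list(genes = genes, family_ids = ids[family_member_indices])
}
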