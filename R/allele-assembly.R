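# Reconstruction of per-accession allelic sequences from quality-filtered
# SNP calls, with the reference-reconstruction validation check, and
# alignment-guided assembly of outgroup sequences in reference coordinates.

#' Translate an in-frame nucleotide sequence
#'
#' @param seq Nucleotide string, length divisible by 3. Codons containing
#'   non-ACGT characters translate to `X`; stops to `*`.
#' @return Amino-acid string.
#' @export
translate_cds <- function(seq) {
  codons <- split_codons(seq)
  code <- Biostrings::GENETIC_CODE
  aa <- unname(code[codons])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Assemble the two allelic sequences of one accession for one region
#'
#' SNP alleles passing the Phred quality filter (`qual >= qual_min`) are
#' substituted into the reference sequence at their chromosomal positions:
#' the alternate alleles give the accession's variant allele, and the
#' records' *stated* reference alleles give a reference-allele
#' reconstruction. The assembly is considered valid only when that
#' reconstruction is 100% identical to the reference sequence — a mismatch
#' signals a coordinate or reference-version error. On minus-strand regions
#' substitution happens in chromosomal space first and both sequences are
#' reverse-complemented afterwards.
#'
#' @param region_interval Chromosomal interval `c(start, end)` (1-based
#'   inclusive) that `reference_seq` covers.
#' @param reference_seq Forward-strand reference sequence of the region.
#' @param snps A [snp_table()]; records outside the interval (or on another
#'   chromosome, if `chrom` is given) are ignored.
#' @param accession Accession id to assemble.
#' @param qual_min Minimum Phred quality for a SNP to be applied
#'   (default 25).
#' @param strand `"+"` or `"-"`; minus-strand output is reverse-complemented.
#' @param chrom Optional chromosome name to filter `snps` on.
#' @return List with `variant` and `reference_check` (character sequences,
#'   coding-strand orientation) and `report`: `accession`,
#'   `n_snps_applied`, `n_snps_filtered_by_quality`, `colzero_identity`
#'   (logical validity flag), `mismatch_pos` (chromosomal positions where
#'   the stated ref allele contradicts the reference).
#' @export
assemble_alleles <- function(region_interval, reference_seq, snps, accession,
                             qual_min = 25, strand = "+", chrom = NULL) {
  a <- region_interval[1L]; b <- region_interval[2L]
  reference_seq <- toupper(reference_seq)
  if (nchar(reference_seq) != b - a + 1L) {
    stop("assemble_alleles: reference length does not match interval")
  }
  df <- as.data.frame(snps)
  df <- df[df$accession == accession, , drop = FALSE]
  if (!is.null(chrom)) df <- df[df$chrom == chrom, , drop = FALSE]
  df <- df[df$pos >= a & df$pos <= b, , drop = FALSE]
  n_filtered <- sum(df$qual < qual_min)
  df <- df[df$qual >= qual_min, , drop = FALSE]
  variant <- strsplit(reference_seq, "", fixed = TRUE)[[1L]]
  recon <- variant
  idx <- df$pos - a + 1L
  mismatch <- df$pos[variant[idx] != df$ref]
  variant[idx] <- df$alt
  recon[idx] <- df$ref
  variant <- paste(variant, collapse = "")
  recon <- paste(recon, collapse = "")
  if (strand == "-") {
    variant <- revcomp(variant)
    recon <- revcomp(recon)
    out_ref <- revcomp(reference_seq)
  } else out_ref <- reference_seq
  list(variant = variant, reference_check = recon,
       report = list(accession = accession,
                     n_snps_applied = nrow(df),
                     n_snps_filtered_by_quality = n_filtered,
                     colzero_identity = identical(recon, out_ref),
                     mismatch_pos = mismatch))
}

#' Assemble a haplotype alignment for a whole accession panel
#'
#' Applies [assemble_alleles()] to every accession in the roster and stacks
#' the variant alleles into a [haplotype_alignment()]. Accessions with no
#' SNP record at a polymorphic site carry the reference allele
#' (`mask_missing = FALSE`, the variant-only-matrix convention) or `N`
#' (`mask_missing = TRUE`).
#'
#' @inheritParams assemble_alleles
#' @param accessions Accessions to assemble (default: the table's roster).
#' @param mask_missing Mask non-called accessions at polymorphic sites
#'   with `N` instead of filling with the reference allele.
#' @param region_id Label for the alignment.
#' @return List with `alignment` (a [haplotype_alignment()]) and `reports`
#'   (list of per-accession assembly reports).
#' @export
assemble_panel <- function(region_interval, reference_seq, snps,
                           accessions = snp_roster(snps), qual_min = 25,
                           strand = "+", chrom = NULL,
                           mask_missing = FALSE, region_id = "region") {
  res <- lapply(accessions, function(acc) {
    assemble_alleles(region_interval, reference_seq, snps, acc,
                     qual_min = qual_min, strand = strand, chrom = chrom)
  })
  seqs <- vapply(res, `[[`, character(1L), "variant")
  m <- matrix(unlist(strsplit(seqs, "", fixed = TRUE)),
              nrow = length(accessions), byrow = TRUE)
  if (mask_missing) {
    df <- as.data.frame(snps)
    if (!is.null(chrom)) df <- df[df$chrom == chrom, , drop = FALSE]
    df <- df[df$pos >= region_interval[1L] & df$pos <= region_interval[2L] &
               df$qual >= qual_min, , drop = FALSE]
    poly_pos <- unique(df$pos)
    for (p in poly_pos) {
      called <- df$accession[df$pos == p]
      col <- p - region_interval[1L] + 1L
      if (strand == "-") col <- nchar(reference_seq) - col + 1L
      m[!(accessions %in% called), col] <- "N"
    }
  }
  coords <- region_interval[1L]:region_interval[2L]
  if (strand == "-") coords <- rev(coords)
  list(alignment = haplotype_alignment(m, accessions = accessions,
                                       region_id = region_id,
                                       coords = coords, chrom = chrom %||% NA_character_),
       reports = lapply(res, `[[`, "report"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Global (Needleman-Wunsch) protein alignment
#'
#' Optimal global alignment under linear gap scoring. Ties in the dynamic
#' program are broken by preferring a match/mismatch step, then a gap in
#' `a`, then a gap in `b`, making the traceback deterministic.
#'
#' @param a,b Non-empty protein (or any character) sequences.
#' @param match,mismatch,gap Scores (defaults 1, -1, -2).
#' @return List with `aligned_a`, `aligned_b` (equal-length strings with
#'   `-` gaps) and `score`.
#' @export
align_proteins_global <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  if (!nzchar(a) || !nzchar(b)) stop("align_proteins_global: empty sequence")
  A <- strsplit(toupper(a), "", fixed = TRUE)[[1L]]
  B <- strsplit(toupper(b), "", fixed = TRUE)[[1L]]
  n <- length(A); m <- length(B)
  S <- matrix(0, n + 1L, m + 1L)
  S[, 1L] <- gap * (0:n)
  S[1L, ] <- gap * (0:m)
  for (i in seq_len(n)) {
    sub <- ifelse(B == A[i], match, mismatch)
    for (j in seq_len(m)) {
      S[i + 1L, j + 1L] <- max(S[i, j] + sub[j],      # diagonal
                               S[i + 1L, j] + gap,    # gap in a (consume b)
                               S[i, j + 1L] + gap)    # gap in b (consume a)
    }
  }
  # traceback, tie preference: diagonal > gap-in-a > gap-in-b
  ra <- character(0); rb <- character(0)
  i <- n; j <- m
  while (i > 0L || j > 0L) {
    if (i > 0L && j > 0L &&
        S[i + 1L, j + 1L] == S[i, j] + (if (A[i] == B[j]) match else mismatch)) {
      ra <- c(A[i], ra); rb <- c(B[j], rb); i <- i - 1L; j <- j - 1L
    } else if (j > 0L && S[i + 1L, j + 1L] == S[i + 1L, j] + gap) {
      ra <- c("-", ra); rb <- c(B[j], rb); j <- j - 1L
    } else {
      ra <- c(A[i], ra); rb <- c("-", rb); i <- i - 1L
    }
  }
  list(aligned_a = paste(ra, collapse = ""),
       aligned_b = paste(rb, collapse = ""),
       score = S[n + 1L, m + 1L])
}

#' Assemble an outgroup CDS in reference coordinate space
#'
#' Projects an outgroup coding sequence onto the reference frame using a
#' protein alignment of their translations: alignment columns where the
#' *reference* protein has a gap are removed (the outgroup codon is
#' dropped), and columns where the *outgroup* has a gap become `---`
#' placeholders. The result always has the length of the reference CDS, so
#' it can be compared codon-by-codon downstream (gap codons are excluded
#' there by [build_codon_alignment()]).
#'
#' @param ref_cds Reference coding sequence (length divisible by 3).
#' @param outgroup_cds Outgroup coding sequence (length divisible by 3).
#' @param protein_alignment Result of [align_proteins_global()] on the two
#'   translations (reference as `a`); computed internally when omitted.
#' @return Nucleotide string of length `nchar(ref_cds)`.
#' @export
assemble_outgroup <- function(ref_cds, outgroup_cds, protein_alignment = NULL) {
  if (nchar(ref_cds) %% 3L || nchar(outgroup_cds) %% 3L) {
    stop("assemble_outgroup: CDS length not divisible by 3")
  }
  if (is.null(protein_alignment)) {
    protein_alignment <- align_proteins_global(translate_cds(ref_cds),
                                               translate_cds(outgroup_cds))
  }
  pa <- strsplit(protein_alignment$aligned_a, "", fixed = TRUE)[[1L]]
  pb <- strsplit(protein_alignment$aligned_b, "", fixed = TRUE)[[1L]]
  if (sum(pa != "-") * 3L != nchar(ref_cds)) {
    stop("assemble_outgroup: alignment does not match reference CDS length")
  }
  if (sum(pb != "-") * 3L != nchar(outgroup_cds)) {
    stop("assemble_outgroup: alignment does not match outgroup CDS length")
  }
  out_codons <- split_codons(outgroup_cds)
  res <- character(0)
  oi <- 0L
  for (k in seq_along(pa)) {
    if (pb[k] != "-") oi <- oi + 1L
    if (pa[k] == "-") next                 # ref gap: drop outgroup codon
    res <- c(res, if (pb[k] == "-") "---" else out_codons[oi])
  }
  paste(res, collapse = "")
}
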