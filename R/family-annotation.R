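# Structural annotation of family members: 500-bp flanking regions, intron
# counts from exon structure, and the tandem-duplication rule (<= 5
# intervening genes AND within 10 kb).

#' Reverse-complement a nucleotide string
#' @param seq Character scalar over `A,C,G,T,N,-` (case preserved as upper).
#' @return Character scalar.
#' @export
revcomp <- function(seq) {
  chartr("ACGTN", "TGCAN",
         paste(rev(strsplit(toupper(seq), "", fixed = TRUE)[[1L]]),
               collapse = ""))
}

#' Extract upstream / CDS / downstream regions of a gene
#'
#' Regions are defined relative to the coding strand: `up` is the `up_len`
#' bases immediately 5' of the start codon and `dn` the `dn_len` bases
#' immediately 3' of the stop codon; on the minus strand the chromosomal
#' intervals are mirrored and the sequences reverse-complemented. The CDS is
#' spliced from the gene's exons. Regions running off a chromosome end are
#' truncated (not padded) and flagged.
#'
#' @param gene A [gene_model()].
#' @param reference Named character vector of chromosome sequences (or a
#'   single unnamed sequence when the gene's chromosome is implicit).
#' @param up_len,dn_len Flanking lengths in bp (defaults 500, the
#'   promoter/terminator windows used throughout the analysis).
#' @return List of class `gene_regions`: `gene_id`, `strand`, and for each
#'   of `up`, `cds`, `dn` a list with `seq` (coding-strand orientation),
#'   `interval` (chromosomal 1-based inclusive `c(start, end)`, or `NULL`
#'   when empty) and `truncated` (up/dn only).
#' @export
extract_regions <- function(gene, reference, up_len = 500L, dn_len = 500L) {
  chrom_seq <- if (is.null(names(reference))) reference[[1L]] else {
    if (!gene$chrom %in% names(reference)) {
      stop("extract_regions: chromosome ", gene$chrom, " not in reference")
    }
    reference[[gene$chrom]]
  }
  chrom_seq <- toupper(chrom_seq)
  clen <- nchar(chrom_seq)
  if (gene$start < 1L || gene$end > clen) {
    stop("extract_regions: gene ", gene$gene_id, " beyond chromosome bounds")
  }
  sub_fwd <- function(a, b) substr(chrom_seq, a, b)
  take <- function(a, b) {
    # truncate at chromosome ends
    ta <- max(a, 1L); tb <- min(b, clen)
    if (ta > tb) return(list(seq = "", interval = NULL, truncated = TRUE))
    list(seq = sub_fwd(ta, tb), interval = c(ta, tb),
         truncated = (ta != a || tb != b))
  }
  if (gene$strand == "+") {
    up <- take(gene$start - up_len, gene$start - 1L)
    dn <- take(gene$end + 1L, gene$end + dn_len)
  } else {
    up <- take(gene$end + 1L, gene$end + up_len)
    dn <- take(gene$start - dn_len, gene$start - 1L)
    up$seq <- revcomp(up$seq)
    dn$seq <- revcomp(dn$seq)
  }
  cds_seq <- paste(mapply(sub_fwd, gene$exons$start, gene$exons$end),
                   collapse = "")
  if (gene$strand == "-") cds_seq <- revcomp(cds_seq)
  structure(
    list(gene_id = gene$gene_id, strand = gene$strand, chrom = gene$chrom,
         up = up,
         cds = list(seq = cds_seq,
                    interval = c(min(gene$exons$start), max(gene$exons$end)),
                    exons = gene$exons),
         dn = dn),
    class = "gene_regions")
}

#' Number of introns of a gene
#'
#' Simply `number of exons - 1`: introns are the gaps between consecutive
#' annotated coding exons.
#'
#' @param gene A [gene_model()] with at least one exon.
#' @return Non-negative integer.
#' @export
count_introns <- function(gene) {
  nrow(gene$exons) - 1L
}

#' Find tandemly duplicated family members
#'
#' Two family genes form a tandem pair when they are on the same chromosome,
#' at most `max_intervening` annotated genes (of any family) lie strictly
#' between them, AND their nearest boundaries are within `max_distance`
#' (start of the downstream gene minus end of the upstream gene). Both
#' conditions are required. Set `distance_mode = "start"` to measure the
#' distance between gene starts instead.
#'
#' @param genes List of [gene_model()] objects sorted by chromosome then
#'   start (unsorted input raises an error).
#' @param family_ids Gene ids belonging to the family of interest.
#' @param max_intervening Maximum number of annotated genes strictly between
#'   the pair (default 5).
#' @param max_distance Maximum distance in bp (default 10000).
#' @param distance_mode `"boundary"` (default) or `"start"`.
#' @return Data.frame with columns `gene_a`, `gene_b` (gene order within a
#'   pair follows the chromosome), `n_intervening`, `distance`.
#' @export
find_tandem_duplicates <- function(genes, family_ids, max_intervening = 5L,
                                   max_distance = 10000L,
                                   distance_mode = c("boundary", "start")) {
  distance_mode <- match.arg(distance_mode)
  chroms <- vapply(genes, `[[`, character(1L), "chrom")
  starts <- vapply(genes, `[[`, integer(1L), "start")
  ends <- vapply(genes, `[[`, integer(1L), "end")
  ids <- vapply(genes, `[[`, character(1L), "gene_id")
  ord <- order(chroms, starts)
  if (!identical(ord, seq_along(genes))) {
    stop("find_tandem_duplicates: genes must be sorted by chromosome then start")
  }
  fam <- which(ids %in% family_ids)
  out <- list()
  if (length(fam) >= 2L) {
    for (x in seq_len(length(fam) - 1L)) {
      for (y in (x + 1L):length(fam)) {
        i <- fam[x]; j <- fam[y]
        if (chroms[i] != chroms[j]) next
        n_between <- sum(chroms == chroms[i] & seq_along(genes) > i &
                           seq_along(genes) < j)
        dist <- if (distance_mode == "boundary") starts[j] - ends[i]
                else starts[j] - starts[i]
        if (n_between <= max_intervening && dist <= max_distance) {
          out[[length(out) + 1L]] <- data.frame(
            gene_a = ids[i], gene_b = ids[j],
            n_intervening = n_between, distance = dist,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(out)) {
    return(data.frame(gene_a = character(), gene_b = character(),
                      n_intervening = integer(), distance = integer(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}
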