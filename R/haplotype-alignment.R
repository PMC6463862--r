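# Haplotype alignments: n assembled allelic sequences x L sites for one
# region. The substrate for all diversity statistics.

#' Construct a haplotype alignment
#'
#' @param seqs Character matrix (accessions x sites) over `A,C,G,T,N`, or a
#'   character vector of equal-length sequence strings.
#' @param accessions Row (accession) ids; defaults to names/rownames.
#' @param region_id Label for the region the alignment covers.
#' @param coords Optional integer vector of chromosomal positions, one per
#'   column, mapping alignment sites back to the chromosome.
#' @param chrom Optional chromosome name for `coords`.
#' @return An object of class `haplotype_alignment`.
#' @export
haplotype_alignment <- function(seqs, accessions = NULL, region_id = "region",
                                coords = NULL, chrom = NA_character_) {
  if (is.character(seqs) && !is.matrix(seqs)) {
    L <- unique(nchar(seqs))
    if (length(L) != 1L) stop("haplotype_alignment: unequal sequence lengths")
    if (is.null(accessions)) accessions <- names(seqs)
    seqs <- matrix(unlist(strsplit(toupper(seqs), "", fixed = TRUE)),
                   nrow = length(seqs), byrow = TRUE)
  } else {
    seqs <- toupper(as.matrix(seqs))
    if (is.null(accessions)) accessions <- rownames(seqs)
  }
  if (is.null(accessions)) accessions <- paste0("seq", seq_len(nrow(seqs)))
  if (nrow(seqs) < 1L) stop("haplotype_alignment: need at least one sequence")
  bad <- !(seqs %in% c("A", "C", "G", "T", "N", "-"))
  if (any(bad)) stop("haplotype_alignment: invalid characters: ",
                     paste(unique(seqs[bad]), collapse = ","))
  if (!is.null(coords) && length(coords) != ncol(seqs)) {
    stop("haplotype_alignment: coords length != number of sites")
  }
  dimnames(seqs) <- list(accessions, NULL)
  structure(list(region_id = region_id, accessions = as.character(accessions),
                 seq = seqs, coords = if (is.null(coords)) NULL else as.integer(coords),
                 chrom = chrom),
            class = "haplotype_alignment")
}

#' @export
print.haplotype_alignment <- function(x, ...) {
  cat(sprintf("<haplotype_alignment> %s: %d sequences x %d sites\n",
              x$region_id, nrow(x$seq), ncol(x$seq)))
  invisible(x)
}

#' Number of sequences / alignment length
#' @param aln A `haplotype_alignment`.
#' @return Integer.
#' @export
aln_n <- function(aln) nrow(aln$seq)

#' @rdname aln_n
#' @export
aln_length <- function(aln) ncol(aln$seq)

#' Extract a column range of an alignment
#' @param aln A `haplotype_alignment`.
#' @param sites Integer vector of column indices to keep.
#' @param region_id Label for the sub-alignment.
#' @return A new `haplotype_alignment`.
#' @export
aln_slice <- function(aln, sites, region_id = aln$region_id) {
  haplotype_alignment(aln$seq[, sites, drop = FALSE],
                      accessions = aln$accessions, region_id = region_id,
                      coords = if (is.null(aln$coords)) NULL else aln$coords[sites],
                      chrom = aln$chrom)
}

#' Subset an alignment by accession
#' @param aln A `haplotype_alignment`.
#' @param accessions Accession ids (or row indices) to keep.
#' @return A new `haplotype_alignment`.
#' @export
aln_subset <- function(aln, accessions) {
  haplotype_alignment(aln$seq[accessions, , drop = FALSE],
                      accessions = if (is.character(accessions)) accessions else
                        aln$accessions[accessions],
                      region_id = aln$region_id, coords = aln$coords,
                      chrom = aln$chrom)
}
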