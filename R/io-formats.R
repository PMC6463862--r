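#' @import Biostrings
#' @importFrom stats median optim optimize qbeta qchisq rbinom rexp rnorm
#'   runif rpois setNames wilcox.test cutree dist hclust sd p.adjust
#' @importFrom utils read.delim write.table combn
NULL

# ---------------------------------------------------------------------------
# Domain types
# ---------------------------------------------------------------------------

#' Construct a gene model
#'
#' A gene model is the minimal structural description of one gene used
#' throughout the pipeline: chromosomal extent, strand, and the ordered coding
#' exons. All coordinates are 1-based inclusive (GFF3 convention); conversion
#' to other conventions happens only at format boundaries.
#'
#' @param gene_id Gene identifier (character scalar).
#' @param chrom Chromosome/scaffold name.
#' @param strand `"+"` or `"-"`.
#' @param start,end 1-based inclusive chromosomal extent of the gene.
#' @param exons Two-column matrix or data.frame of exon `start`, `end`
#'   (1-based inclusive, chromosomal coordinates). Exons must lie inside
#'   `[start, end]`, be pairwise non-overlapping, and are stored sorted by
#'   chromosomal start regardless of strand.
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene_id, chrom, strand, start, end, exons) {
  stopifnot(is.character(gene_id), length(gene_id) == 1L)
  strand <- as.character(strand)
  if (!strand %in% c("+", "-")) {
    stop("strand must be '+' or '-', got: ", strand)
  }
  start <- as.integer(start); end <- as.integer(end)
  if (start > end) stop("gene ", gene_id, ": start > end")
  exons <- as.data.frame(exons)
  names(exons)[1:2] <- c("start", "end")
  exons$start <- as.integer(exons$start)
  exons$end <- as.integer(exons$end)
  exons <- exons[order(exons$start), , drop = FALSE]
  rownames(exons) <- NULL
  if (nrow(exons) == 0L) stop("gene ", gene_id, ": no exons")
  if (any(exons$start > exons$end)) stop("gene ", gene_id, ": exon start > end")
  if (any(exons$start < start) || any(exons$end > end)) {
    stop("gene ", gene_id, ": exon outside gene extent")
  }
  if (nrow(exons) > 1L &&
      any(exons$start[-1L] <= exons$end[-nrow(exons)])) {
    stop("gene ", gene_id, ": overlapping exons")
  }
  structure(
    list(gene_id = gene_id, chrom = chrom, strand = strand,
         start = start, end = end, exons = exons),
    class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s %s:%d-%d(%s), %d exon(s)\n",
              x$gene_id, x$chrom, x$start, x$end, x$strand, nrow(x$exons)))
  invisible(x)
}

#' Construct a SNP table
#'
#' A SNP table holds per-accession biallelic SNP calls: one row per
#' (accession, chrom, pos) carrying the alternate allele, with its Phred
#' quality. Accessions absent at a position are assumed to carry the
#' reference allele (variant-only convention of resequencing SNP matrices).
#'
#' @param df Data frame with columns `accession`, `chrom`, `pos`, `ref`,
#'   `alt`, `qual`.
#' @param roster Character vector of all accession ids in the panel
#'   (defaults to the accessions present in `df`). Needed so allele
#'   frequencies can be computed under the reference-fill convention.
#' @return A `snp_table` (a data.frame subclass with a `roster` attribute).
#' @export
snp_table <- function(df, roster = NULL) {
  req <- c("accession", "chrom", "pos", "ref", "alt", "qual")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("snp_table: missing columns: ", paste(miss, collapse = ", "))
  df <- as.data.frame(df)[req]
  df$accession <- as.character(df$accession)
  df$chrom <- as.character(df$chrom)
  df$pos <- as.integer(df$pos)
  df$ref <- toupper(as.character(df$ref))
  df$alt <- toupper(as.character(df$alt))
  df$qual <- as.numeric(df$qual)
  bad <- !(df$ref %in% c("A", "C", "G", "T")) | !(df$alt %in% c("A", "C", "G", "T"))
  if (any(bad)) stop("snp_table: non-ACGT alleles in ", sum(bad), " record(s)")
  if (any(df$ref == df$alt)) stop("snp_table: ref == alt in some records")
  if (any(df$qual < 0)) stop("snp_table: negative quality")
  key <- paste(df$accession, df$chrom, df$pos, sep = "\r")
  if (anyDuplicated(key)) {
    stop("snp_table: duplicate (accession, chrom, pos) records: ",
         sum(duplicated(key)))
  }
  if (is.null(roster)) roster <- sort(unique(df$accession))
  if (!all(df$accession %in% roster)) {
    stop("snp_table: records for accessions not in roster")
  }
  rownames(df) <- NULL
  structure(df, roster = as.character(roster),
            class = c("snp_table", "data.frame"))
}

#' Accession roster of a SNP table
#' @param x A `snp_table`.
#' @return Character vector of accession ids.
#' @export
snp_roster <- function(x) attr(x, "roster")

#' Validate an accession metadata table
#'
#' @param df Data frame with columns `accession`, `latitude`, `longitude`
#'   and optionally `altitude` (metres or free text, kept as-is).
#' @return The validated data.frame.
#' @export
accession_metadata <- function(df) {
  req <- c("accession", "latitude", "longitude")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("accession_metadata: missing columns: ",
                         paste(miss, collapse = ", "))
  df <- as.data.frame(df)
  df$accession <- as.character(df$accession)
  df$latitude <- as.numeric(df$latitude)
  df$longitude <- as.numeric(df$longitude)
  if (anyDuplicated(df$accession)) stop("accession_metadata: duplicate accessions")
  ok <- is.na(df$latitude) | (df$latitude >= -90 & df$latitude <= 90)
  if (!all(ok)) stop("accession_metadata: latitude outside [-90, 90]")
  df
}

#' Validate an expression matrix
#'
#' Genes in rows, accessions in columns, RPKM values (non-negative reals).
#'
#' @param m Numeric matrix with unique row and column names.
#' @return The validated matrix.
#' @export
expression_matrix <- function(m) {
  m <- as.matrix(m)
  storage.mode(m) <- "double"
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop("expression_matrix: row and column names required")
  }
  if (anyDuplicated(rownames(m)) || anyDuplicated(colnames(m))) {
    stop("expression_matrix: duplicate row or column labels")
  }
  if (any(m < 0, na.rm = TRUE)) stop("expression_matrix: negative RPKM values")
  m
}

# ---------------------------------------------------------------------------
# FASTA
# ---------------------------------------------------------------------------

#' Read a FASTA file
#'
#' Sequences are upper-cased; record order is preserved. Record ids are the
#' header up to the first whitespace.
#'
#' @param path Path to a FASTA file (nucleotide or protein).
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  lines <- readLines(path)
  nonblank <- which(nzchar(trimws(lines)))
  if (!length(nonblank)) stop("read_fasta: empty file: ", path)
  first <- nonblank[1L]
  if (!startsWith(lines[first], ">")) {
    stop("read_fasta: line ", first, " is not a FASTA header: ", lines[first])
  }
  hdr <- which(startsWith(lines, ">"))
  starts <- hdr + 1L
  ends <- c(hdr[-1L] - 1L, length(lines))
  ids <- sub("\\s.*$", "", sub("^>", "", lines[hdr]))
  if (any(!nzchar(ids))) {
    stop("read_fasta: malformed (empty) header at line ", hdr[!nzchar(ids)][1L])
  }
  seqs <- vapply(seq_along(hdr), function(i) {
    if (starts[i] > ends[i]) return("")
    toupper(gsub("\\s", "", paste(lines[starts[i]:ends[i]], collapse = "")))
  }, character(1L))
  empty <- !nzchar(seqs)
  if (any(empty)) {
    stop("read_fasta: empty sequence for record '", ids[empty][1L],
         "' at line ", hdr[empty][1L])
  }
  setNames(seqs, ids)
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
  x <- Biostrings::BStringSet(unname(as.character(seqs)))
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, filepath = path, width = width)
  invisible(path)
}

# ---------------------------------------------------------------------------
# GFF3
# ---------------------------------------------------------------------------

#' Read gene models from a GFF3 file
#'
#' One `gene_model` is built per `gene` feature. Exons are taken from the CDS
#' features of the gene's primary transcript (the first mRNA by coordinate
#' then id); CDS features attached directly to a gene are also accepted.
#'
#' @param path Path to a GFF3 file.
#' @return List of `gene_model` objects, in file order of the gene features.
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  typ <- as.character(gr$type)
  ids <- as.character(gr$ID)
  parents <- gr$Parent  # CharacterList
  has_parent <- lengths(parents) > 0L
  parent1 <- rep(NA_character_, length(gr))
  parent1[has_parent] <- vapply(parents[has_parent], `[`, character(1L), 1L)
  known <- ids[!is.na(ids)]
  orphan <- has_parent & !(parent1 %in% known)
  if (any(orphan)) {
    stop("read_gff3: feature(s) with unknown Parent: ",
         paste(unique(parent1[orphan]), collapse = ", "))
  }
  gene_idx <- which(typ == "gene")
  if (!length(gene_idx)) stop("read_gff3: no gene features in ", path)
  lapply(gene_idx, function(gi) {
    gid <- ids[gi]
    if (is.na(gid)) stop("read_gff3: gene feature without ID attribute")
    mrna_idx <- which(typ %in% c("mRNA", "transcript") & parent1 == gid)
    if (length(mrna_idx)) {
      ord <- order(GenomicRanges::start(gr)[mrna_idx], ids[mrna_idx])
      tx_id <- ids[mrna_idx[ord[1L]]]
      cds_idx <- which(typ == "CDS" & parent1 == tx_id)
    } else {
      cds_idx <- which(typ == "CDS" & parent1 == gid)
    }
    if (!length(cds_idx)) {
      # fall back to exon features when no CDS is annotated
      src <- if (length(mrna_idx)) ids[mrna_idx[1L]] else gid
      cds_idx <- which(typ == "exon" & parent1 == src)
    }
    if (!length(cds_idx)) stop("read_gff3: gene ", gid, " has no CDS/exon features")
    gene_model(
      gene_id = gid,
      chrom = as.character(GenomicRanges::seqnames(gr))[gi],
      strand = as.character(GenomicRanges::strand(gr))[gi],
      start = GenomicRanges::start(gr)[gi],
      end = GenomicRanges::end(gr)[gi],
      exons = data.frame(start = GenomicRanges::start(gr)[cds_idx],
                         end = GenomicRanges::end(gr)[cds_idx]))
  })
}

#' Write gene models to a GFF3 file
#'
#' Emits gene, mRNA and CDS features (one synthetic transcript per gene) so
#' that [read_gff3()] on the output reconstructs the same models.
#'
#' @param genes List of `gene_model` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path) {
  rows <- lapply(genes, function(g) {
    tx <- paste0(g$gene_id, ".t1")
    rbind(
      data.frame(seqid = g$chrom, source = "askpoly", type = "gene",
                 start = g$start, end = g$end, score = ".", strand = g$strand,
                 phase = ".", attributes = paste0("ID=", g$gene_id)),
      data.frame(seqid = g$chrom, source = "askpoly", type = "mRNA",
                 start = g$start, end = g$end, score = ".", strand = g$strand,
                 phase = ".", attributes = paste0("ID=", tx, ";Parent=", g$gene_id)),
      data.frame(seqid = g$chrom, source = "askpoly", type = "CDS",
                 start = g$exons$start, end = g$exons$end, score = ".",
                 strand = g$strand, phase = ".",
                 attributes = paste0("ID=", tx, ".cds;Parent=", tx)))
  })
  tab <- do.call(rbind, rows)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  write.table(tab, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# SNP calls (VCF / TSV)
# ---------------------------------------------------------------------------

#' Read per-accession SNP calls
#'
#' Two dialects are supported. `"tsv"` is the canonical exchange format:
#' a tab-separated file with header columns `accession`, `chrom`, `pos`,
#' `ref`, `alt`, `qual`, one row per accession carrying the alternate allele.
#' `"vcf"` reads a VCF (v4.x) with per-sample GT fields; every sample whose
#' genotype includes the alternate allele yields one record (heterozygous
#' calls take the alternate allele and are counted in the skip log — the
#' panel is treated as inbred haploid). Indel and multi-allelic rows, and
#' rows whose REF is not a single A/C/G/T, are skipped and counted.
#'
#' @param path Input file.
#' @param dialect `"vcf"` or `"tsv"`.
#' @param roster Optional accession roster (defaults to VCF samples, or the
#'   accessions present in a TSV).
#' @return A [snp_table()]; attribute `skipped` holds named skip counts
#'   (`indel`, `multiallelic`, `bad_ref`, `het_as_alt`).
#' @export
read_snps <- function(path, dialect = c("tsv", "vcf"), roster = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") {
    df <- read.delim(path, stringsAsFactors = FALSE)
    st <- snp_table(df, roster = roster)
    attr(st, "skipped") <- c(indel = 0L, multiallelic = 0L,
                             bad_ref = 0L, het_as_alt = 0L)
    return(st)
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  samples <- colnames(gt)
  if (is.null(roster)) roster <- samples
  ref <- toupper(fix$REF); alt <- toupper(fix$ALT)
  multi <- grepl(",", alt, fixed = TRUE)
  indel <- !multi & (nchar(ref) != 1L | nchar(alt) != 1L)
  bad_ref <- !multi & !indel & !(ref %in% c("A", "C", "G", "T"))
  keep <- !(multi | indel | bad_ref)
  het_n <- 0L
  out <- vector("list", sum(keep))
  ki <- 0L
  for (i in which(keep)) {
    g <- gt[i, ]
    alleles <- strsplit(gsub("\\|", "/", g), "/", fixed = FALSE)
    has_alt <- vapply(alleles, function(a) any(a == "1"), logical(1L))
    has_alt[is.na(g)] <- FALSE
    het <- vapply(alleles, function(a) any(a == "1") && any(a == "0"), logical(1L))
    het[is.na(g)] <- FALSE
    het_n <- het_n + sum(het)
    if (!any(has_alt)) next
    ki <- ki + 1L
    out[[ki]] <- data.frame(
      accession = samples[has_alt], chrom = fix$CHROM[i],
      pos = as.integer(fix$POS[i]), ref = ref[i], alt = alt[i],
      qual = as.numeric(fix$QUAL[i]), stringsAsFactors = FALSE)
  }
  df <- if (ki) do.call(rbind, out[seq_len(ki)]) else
    data.frame(accession = character(), chrom = character(), pos = integer(),
               ref = character(), alt = character(), qual = numeric())
  st <- snp_table(df, roster = roster)
  attr(st, "skipped") <- c(indel = sum(indel), multiallelic = sum(multi),
                           bad_ref = sum(bad_ref), het_as_alt = het_n)
  st
}

#' Write a SNP table in the TSV dialect
#' @param snps A `snp_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_snps_tsv <- function(snps, path) {
  write.table(as.data.frame(snps), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
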