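ref3k <- local({
  set.seed(42)
  paste(sample(c("A", "C", "G", "T"), 3000, replace = TRUE), collapse = "")
})

test_that("extract_regions computes flanking intervals on the plus strand", {
  g <- gene_model("g1", "chr1", "+", 1001L, 1900L,
                  exons = data.frame(start = 1001L, end = 1900L))
  r <- extract_regions(g, c(chr1 = ref3k))
  expect_identical(r$up$interval, c(501L, 1000L))
  expect_identical(r$dn$interval, c(1901L, 2400L))
  expect_false(r$up$truncated)
  expect_identical(r$up$seq, substr(ref3k, 501, 1000))
  expect_identical(r$cds$seq, substr(ref3k, 1001, 1900))
})

test_that("regions are truncated and flagged at chromosome ends", {
  g <- gene_model("g1", "chr1", "+", 1L, 90L,
                  exons = data.frame(start = 1L, end = 90L))
  r <- extract_regions(g, c(chr1 = ref3k))
  expect_identical(r$up$seq, "")
  expect_null(r$up$interval)
  expect_true(r$up$truncated)
  g2 <- gene_model("g2", "chr1", "+", 2000L, 3100L,
                   exons = data.frame(start = 2000L, end = 3100L))
  expect_error(extract_regions(g2, c(chr1 = ref3k)), "bounds")
})

test_that("minus-strand regions are mirrored and reverse-complemented", {
  g <- gene_model("g1", "chr1", "-", 1001L, 1900L,
                  exons = data.frame(start = 1001L, end = 1900L))
  r <- extract_regions(g, c(chr1 = ref3k))
  expect_identical(r$up$interval, c(1901L, 2400L))
  expect_identical(r$dn$interval, c(501L, 1000L))
  # manual reverse-complement check
  fwd <- substr(ref3k, 1901, 2400)
  manual <- chartr("ACGT", "TGCA",
                   paste(rev(strsplit(fwd, "")[[1L]]), collapse = ""))
  expect_identical(r$up$seq, manual)
  expect_identical(r$cds$seq, revcomp(substr(ref3k, 1001, 1900)))
})

test_that("relocating an extracted region recovers its stated interval", {
  for (strand in c("+", "-")) {
    g <- gene_model("g", "chr1", strand, 901L, 1300L,
                    exons = data.frame(start = 901L, end = 1300L))
    r <- extract_regions(g, c(chr1 = ref3k), up_len = 120L, dn_len = 80L)
    for (reg in list(r$up, r$dn)) {
      chrspace <- if (strand == "-") revcomp(reg$seq) else reg$seq
      hit <- regexpr(chrspace, ref3k, fixed = TRUE)
      expect_identical(as.integer(hit), reg$interval[1L])
      expect_identical(nchar(chrspace), reg$interval[2L] - reg$interval[1L] + 1L)
    }
  }
})

test_that("intron count is exon count minus one", {
  mk <- function(n_ex) {
    ex <- data.frame(start = seq(1L, by = 200L, length.out = n_ex),
                     end = seq(100L, by = 200L, length.out = n_ex))
    gene_model("g", "chr1", "+", 1L, max(ex$end), exons = ex)
  }
  expect_identical(count_introns(mk(1L)), 0L)
  expect_identical(count_introns(mk(2L)), 1L)
  expect_identical(count_introns(mk(4L)), 3L)
})

test_that("tandem duplication rule requires both spacing conditions", {
  # family pair with 3 intervening genes and an 8 kb boundary gap: reported
  gt <- generate_gene_table(5, c(1, 5), gaps = c(400L, 400L, 400L, 400L),
                            gene_length = 1500L)
  # boundary gap gene1 -> gene5: 4 gaps + 3 gene bodies = 6097 <= 10 kb,
  # 3 intervening genes
  hits <- find_tandem_duplicates(gt$genes, gt$family_ids)
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$n_intervening, 3L)
  expect_identical(hits$distance, 4L * 400L + 3L * 1499L)

  # 12 kb apart with 2 intervening: distance fails, not reported
  far <- generate_gene_table(4, c(1, 4), gaps = c(400L, 10000L, 400L),
                             gene_length = 600L)
  expect_identical(nrow(find_tandem_duplicates(far$genes, far$family_ids)), 0L)

  # 6 intervening genes within 10 kb: count fails, not reported
  crowded <- generate_gene_table(8, c(1, 8), gaps = rep(100L, 7L),
                                 gene_length = 100L)
  expect_identical(nrow(find_tandem_duplicates(crowded$genes,
                                               crowded$family_ids)), 0L)
})

test_that("tandem pairs never span chromosomes and need sorted input", {
  g1 <- gene_model("a", "chr1", "+", 100L, 200L,
                   exons = data.frame(start = 100L, end = 200L))
  g2 <- gene_model("b", "chr2", "+", 300L, 400L,
                   exons = data.frame(start = 300L, end = 400L))
  expect_identical(nrow(find_tandem_duplicates(list(g1, g2), c("a", "b"))), 0L)
  expect_error(find_tandem_duplicates(list(g2, g1), c("a", "b")), "sorted")
})

test_that("the tandem relation is symmetric, irreflexive and order-robust", {
  gt <- generate_gene_table(7, c(2, 3, 6), gaps = rep(700L, 6L),
                            gene_length = 800L)
  hits <- find_tandem_duplicates(gt$genes, gt$family_ids)
  # no self pairs; each unordered pair reported once
  expect_true(all(hits$gene_a != hits$gene_b))
  key <- apply(hits[, c("gene_a", "gene_b")], 1L, function(r)
    paste(sort(r), collapse = "|"))
  expect_false(anyDuplicated(key) > 0L)
  # re-sorting a reversed gene list yields the same pair set
  rev_sorted <- rev(gt$genes)
  rev_sorted <- rev_sorted[order(vapply(rev_sorted, `[[`, character(1L), "chrom"),
                                 vapply(rev_sorted, `[[`, integer(1L), "start"))]
  hits2 <- find_tandem_duplicates(rev_sorted, gt$family_ids)
  key2 <- apply(hits2[, c("gene_a", "gene_b")], 1L, function(r)
    paste(sort(r), collapse = "|"))
  expect_setequal(key, key2)
})

test_that("start-to-start distance mode is available", {
  gt <- generate_gene_table(2, c(1, 2), gaps = 9000L, gene_length = 2000L)
  # boundary gap 9000 passes; start-start distance 11000 fails
  expect_identical(nrow(find_tandem_duplicates(gt$genes, gt$family_ids)), 1L)
  expect_identical(nrow(find_tandem_duplicates(gt$genes, gt$family_ids,
                                               distance_mode = "start")), 0L)
})
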