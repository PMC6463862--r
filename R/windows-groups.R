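# Sliding-window diversity over promoter regions, latitude / expression
# grouping of accessions, and rank-sum group comparisons.

#' Sliding-window nucleotide diversity
#'
#' Tiles windows of `window` bp every `step` bp across the alignment,
#' anchored at the 3' end: the last alignment column sits at offset -1
#' (immediately upstream of the anchor, e.g. a transcription start site) and
#' the first at offset -L. A 2500-bp region with the default 200/100 window
#' yields 24 windows starting at offsets -2500, -2400, ..., -200. Per-window
#' pi is per site, computed as in [nucleotide_diversity()].
#'
#' @param aln A [haplotype_alignment()], length >= `window`.
#' @param window Window length in bp (default 200).
#' @param step Slide in bp (default 100).
#' @return Data.frame of class `window_profile`: `window`, `start_offset`,
#'   `end_offset`, `start_col`, `end_col`, `pi_site`.
#' @export
sliding_window_diversity <- function(aln, window = 200L, step = 100L) {
  L <- aln_length(aln)
  if (window > L) stop("sliding_window_diversity: window longer than region")
  n_win <- (L - window) %/% step + 1L
  k <- seq_len(n_win)
  start_col <- (k - 1L) * step + 1L
  end_col <- start_col + window - 1L
  # per-site discordant pair counts once, then window sums via cumsum
  n <- aln_n(aln)
  cnt <- site_allele_counts(aln)
  m <- rowSums(cnt)
  disc <- m * (m - 1) / 2 - rowSums(cnt * (cnt - 1) / 2)
  cum <- c(0, cumsum(disc))
  pi_site <- (cum[end_col + 1L] - cum[start_col]) /
    (n * (n - 1) / 2) / window
  structure(data.frame(window = k,
                       start_offset = start_col - L - 1L,
                       end_offset = end_col - L - 1L,
                       start_col = start_col, end_col = end_col,
                       pi_site = pi_site),
            class = c("window_profile", "data.frame"))
}

#' Assign accessions to latitude bins
#'
#' Bins are left-closed, right-open, except the last which is closed on the
#' right (defaults: `[40,45)`, `[45,50)`, `[50,60]` degrees N). Accessions
#' outside every bin are unassigned (`NA`).
#'
#' @param metadata An [accession_metadata()] data.frame.
#' @param bins List of `c(lower, upper)` latitude bounds.
#' @return Data.frame `accession`, `latitude`, `group` (labels like
#'   `"40-45"`).
#' @export
assign_latitude_groups <- function(metadata,
                                   bins = list(c(40, 45), c(45, 50), c(50, 60))) {
  lab <- vapply(bins, function(b) paste0(b[1L], "-", b[2L]), character(1L))
  lat <- metadata$latitude
  grp <- rep(NA_character_, length(lat))
  for (i in seq_along(bins)) {
    b <- bins[[i]]
    hit <- !is.na(lat) & lat >= b[1L] &
      (if (i == length(bins)) lat <= b[2L] else lat < b[2L])
    grp[hit & is.na(grp)] <- lab[i]
  }
  data.frame(accession = metadata$accession, latitude = lat, group = grp,
             stringsAsFactors = FALSE)
}

#' Assign accessions to expression-level groups
#'
#' Splits RPKM values into low / medium / high at the given boundaries:
#' low `[range[1], boundaries[1])`, medium `[boundaries[1], boundaries[2])`,
#' high `[boundaries[2], range[2]]`. Values outside `range` are unassigned.
#' Defaults reproduce a 50-137 / 137-170 / 170-480 RPKM split.
#'
#' @param x Named numeric vector of RPKM values (names = accessions), or a
#'   single row of an [expression_matrix()].
#' @param boundaries Two inner cut points.
#' @param range Overall `c(min, max)` of values considered.
#' @return Data.frame `accession`, `value`, `group` in
#'   `c("low", "medium", "high", NA)`.
#' @export
assign_expression_groups <- function(x, boundaries = c(137, 170),
                                     range = c(50, 480)) {
  v <- as.numeric(x)
  acc <- names(x)
  grp <- rep(NA_character_, length(v))
  grp[v >= range[1L] & v < boundaries[1L]] <- "low"
  grp[v >= boundaries[1L] & v < boundaries[2L]] <- "medium"
  grp[v >= boundaries[2L] & v <= range[2L]] <- "high"
  data.frame(accession = acc %||% as.character(seq_along(v)), value = v,
             group = grp, stringsAsFactors = FALSE)
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Midranks for ties; exact p-value by enumeration when
#' `min(n_x, n_y) <= 8` and there are no ties, otherwise the normal
#' approximation with tie and continuity corrections. Two degenerate inputs
#' with every value identical give p = 1.
#'
#' @param x,y Non-empty numeric samples.
#' @param alternative `"two.sided"` (default), `"less"` (x tends smaller)
#'   or `"greater"`.
#' @return List with `U` (Mann-Whitney U of `x`) and `p`.
#' @export
wilcoxon_rank_sum <- function(x, y, alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  if (!length(x) || !length(y)) stop("wilcoxon_rank_sum: empty sample")
  r <- rank(c(x, y))
  U <- sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
  if (length(unique(c(x, y))) == 1L) return(list(U = U, p = 1))
  ties <- anyDuplicated(c(x, y)) > 0L
  use_exact <- !ties && min(length(x), length(y)) <= 8L
  wt <- suppressWarnings(
    wilcox.test(x, y, alternative = alternative, exact = use_exact,
                correct = TRUE))
  list(U = unname(wt$statistic), p = wt$p.value)
}

#' Compare windowed diversity between accession groups
#'
#' For every group a windowed pi profile distribution is built by
#' resampling: `n_resample` subsamples of `floor(resample_fraction * n)`
#' accessions are drawn without replacement and a [sliding_window_diversity()]
#' profile computed on each. Per window, the focal group's resample values
#' are compared to every other group's by [wilcoxon_rank_sum()]. A simpler
#' `mode = "windows"` compares the groups' full-panel per-window pi values
#' across the windows of a band (one test per group pair).
#'
#' The unit of replication for this comparison is a genuinely open
#' methodological choice; both modes are provided and the vignette
#' discusses the trade-off.
#'
#' @param alignments Named list of [haplotype_alignment()] objects (one per
#'   group, equal lengths). Groups with fewer than 2 accessions are skipped
#'   with a warning.
#' @param focal Name of the focal group.
#' @param window,step Window geometry (defaults 200/100).
#' @param mode `"resample"` (default) or `"windows"`.
#' @param n_resample,resample_fraction Resampling design for
#'   `mode = "resample"`.
#' @param band `c(lo, hi)` offsets (e.g. `c(-1600, -500)`) selecting the
#'   windows compared in `mode = "windows"`; windows fully inside the band
#'   are used.
#' @param alpha Significance level for the per-window flags.
#' @param alternative Passed to [wilcoxon_rank_sum()]; `"two.sided"` by
#'   default, use `"greater"` for the directional claim that the focal
#'   group is more diverse.
#' @param adjust `"none"` (default; per-window tests are reported raw) or
#'   `"BH"` for Benjamini-Hochberg across windows.
#' @param seed Integer seed for the resampling.
#' @return For `mode = "resample"`: data.frame with `window`,
#'   `start_offset`, `group`, `pi_focal`, `pi_group` (full-panel values),
#'   `p`, `significant`. For `mode = "windows"`: data.frame with `group`,
#'   `n_windows`, `p`, `significant`.
#' @export
compare_window_profiles <- function(alignments, focal, window = 200L,
                                    step = 100L,
                                    mode = c("resample", "windows"),
                                    n_resample = 100L, resample_fraction = 0.5,
                                    band = NULL, alpha = 0.05,
                                    alternative = "two.sided",
                                    adjust = c("none", "BH"), seed = NULL) {
  mode <- match.arg(mode)
  adjust <- match.arg(adjust)
  if (length(alignments) < 2L) {
    stop("compare_window_profiles: need at least two groups")
  }
  if (!focal %in% names(alignments)) {
    stop("compare_window_profiles: focal group not found")
  }
  small <- vapply(alignments, aln_n, integer(1L)) < 2L
  if (any(small)) {
    warning("compare_window_profiles: skipping group(s) with < 2 accessions: ",
            paste(names(alignments)[small], collapse = ", "))
    alignments <- alignments[!small]
    if (!focal %in% names(alignments) || length(alignments) < 2L) {
      stop("compare_window_profiles: too few usable groups")
    }
  }
  full_profiles <- lapply(alignments, sliding_window_diversity,
                          window = window, step = step)
  others <- setdiff(names(alignments), focal)

  if (mode == "windows") {
    if (is.null(band)) stop("compare_window_profiles: mode='windows' needs a band")
    prof0 <- full_profiles[[focal]]
    in_band <- prof0$start_offset >= band[1L] & prof0$end_offset <= band[2L]
    if (!any(in_band)) stop("compare_window_profiles: no windows inside band")
    out <- lapply(others, function(g) {
      wt <- wilcoxon_rank_sum(prof0$pi_site[in_band],
                              full_profiles[[g]]$pi_site[in_band],
                              alternative = alternative)
      data.frame(group = g, n_windows = sum(in_band), p = wt$p,
                 significant = wt$p < alpha, stringsAsFactors = FALSE)
    })
    return(do.call(rbind, out))
  }

  # one set of resample index draws per distinct group size, shared across
  # groups of that size: identical groups then yield identical profile
  # distributions, and equally-sized groups are compared as paired designs
  sizes <- vapply(alignments, aln_n, integer(1L))
  idx_by_size <- with_seed(seed, {
    out <- list()
    for (n in sort(unique(sizes))) {
      k <- max(2L, floor(resample_fraction * n))
      out[[as.character(n)]] <- lapply(seq_len(n_resample),
                                       function(b) sample.int(n, k))
    }
    out
  })
  resampled <- lapply(alignments, function(aln) {
    idx <- idx_by_size[[as.character(aln_n(aln))]]
    t(vapply(idx, function(rows) {
      sliding_window_diversity(aln_subset(aln, rows),
                               window = window, step = step)$pi_site
    }, numeric(nrow(full_profiles[[1L]]))))
  })
  prof0 <- full_profiles[[focal]]
  out <- list()
  for (g in others) {
    p <- vapply(seq_len(nrow(prof0)), function(w) {
      wilcoxon_rank_sum(resampled[[focal]][, w], resampled[[g]][, w],
                        alternative = alternative)$p
    }, numeric(1L))
    if (adjust == "BH") p <- p.adjust(p, method = "BH")
    out[[g]] <- data.frame(window = prof0$window,
                           start_offset = prof0$start_offset,
                           group = g,
                           pi_focal = prof0$pi_site,
                           pi_group = full_profiles[[g]]$pi_site,
                           p = p, significant = p < alpha,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Group means and pairwise rank-sum comparisons
#'
#' @param values Numeric vector (e.g. one gene's RPKM across accessions).
#' @param groups Group label per value; `NA`-labelled values are dropped.
#' @return List with `summary` (data.frame: `group`, `n`, `mean`, `median`)
#'   and `pairwise` (data.frame: `group_a`, `group_b`, `p`; two-sided
#'   rank-sum).
#' @export
group_mean_comparison <- function(values, groups) {
  keep <- !is.na(groups)
  values <- values[keep]; groups <- as.character(groups)[keep]
  gl <- unique(groups)
  if (length(gl) < 2L) stop("group_mean_comparison: need >= 2 groups")
  if (any(table(groups) == 0L)) stop("group_mean_comparison: empty group")
  summ <- data.frame(
    group = gl,
    n = vapply(gl, function(g) sum(groups == g), integer(1L)),
    mean = vapply(gl, function(g) mean(values[groups == g]), numeric(1L)),
    median = vapply(gl, function(g) median(values[groups == g]), numeric(1L)),
    stringsAsFactors = FALSE)
  pairs <- combn(gl, 2L)
  pw <- data.frame(
    group_a = pairs[1L, ], group_b = pairs[2L, ],
    p = apply(pairs, 2L, function(pr) {
      wilcoxon_rank_sum(values[groups == pr[1L]],
                        values[groups == pr[2L]])$p
    }),
    stringsAsFactors = FALSE)
  list(summary = summ, pairwise = pw)
}
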