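# Pairwise ortholog dN/dS machinery: GY94-style codon substitution model with
# maximum-likelihood fitting, the fixed-vs-free-omega likelihood-ratio test of
# neutral evolution, and the Nei-Gojobori (1986) counting estimator as an
# independent cross-check.

.askpoly_env <- new.env(parent = emptyenv())

#' The 61-codon sense state space and its precomputed change structure
#'
#' Returns (and caches) the universal-code sense codons plus, for every codon
#' pair, whether they differ at exactly one nucleotide, whether that change
#' is a transition, and whether it is nonsynonymous. Also per-codon
#' synonymous site counts for the NG86 estimator (changes to stop codons are
#' counted as nonsynonymous opportunities).
#'
#' @return List: `codons` (61 strings), `aa` (amino acids), `single`, `ts`,
#'   `nonsyn` (61 x 61 logical matrices), `syn_sites` (per-codon synonymous
#'   site count).
#' @export
codon_space <- function() {
  if (!is.null(.askpoly_env$codon_space)) return(.askpoly_env$codon_space)
  nts <- c("T", "C", "A", "G")
  all64 <- apply(expand.grid(nts, nts, nts, stringsAsFactors = FALSE)[, 3:1],
                 1L, paste, collapse = "")
  code <- Biostrings::GENETIC_CODE
  codons <- all64[code[all64] != "*"]
  aa <- unname(code[codons])
  n <- length(codons)
  mat <- do.call(rbind, strsplit(codons, "", fixed = TRUE))
  ndiff <- matrix(0L, n, n)
  for (p in 1:3) ndiff <- ndiff + outer(mat[, p], mat[, p], "!=")
  single <- ndiff == 1L
  is_ts_pair <- function(x, y) (x == "A" & y == "G") | (x == "G" & y == "A") |
    (x == "C" & y == "T") | (x == "T" & y == "C")
  ts <- matrix(FALSE, n, n)
  for (p in 1:3) {
    ts <- ts | (single & outer(mat[, p], mat[, p], is_ts_pair) &
                  (ndiff == 1L) & outer(mat[, p], mat[, p], "!="))
  }
  nonsyn <- outer(aa, aa, "!=")
  # per-codon synonymous sites: fraction of the 9 single-nt neighbours
  # (3 per position) that are synonymous; stop neighbours count as nonsyn
  syn_sites <- numeric(n)
  for (i in seq_len(n)) {
    s <- 0
    for (p in 1:3) {
      for (b in setdiff(nts, mat[i, p])) {
        nb <- codons[i]
        substr(nb, p, p) <- b
        if (code[nb] == aa[i]) s <- s + 1 / 3
      }
    }
    syn_sites[i] <- s
  }
  res <- list(codons = codons, aa = aa, single = single, ts = ts,
              nonsyn = nonsyn,
              syn_sites = setNames(syn_sites, codons))
  .askpoly_env$codon_space <- res
  res
}

codon_index <- function(codon_strings) {
  cs <- codon_space()
  match(codon_strings, cs$codons)
}

split_codons <- function(seq) {
  seq <- toupper(seq)
  if (nchar(seq) %% 3L != 0L) stop("sequence length not divisible by 3")
  substring(seq, seq(1L, nchar(seq), 3L), seq(3L, nchar(seq), 3L))
}

# ---------------------------------------------------------------------------
# Codon alignment
# ---------------------------------------------------------------------------

#' Build a pairwise codon alignment
#'
#' Takes two equal-length in-frame nucleotide sequences (e.g. a reference CDS
#' and the outgroup sequence projected into its coordinate space by
#' [assemble_outgroup()]) and drops every codon column containing a gap, an
#' ambiguous base, or a stop codon in either sequence. Internal stops are
#' dropped with a warning since they may indicate pseudogenisation.
#'
#' @param ref_cds,outgroup_cds Nucleotide strings of equal length divisible
#'   by 3.
#' @return Object of class `codon_alignment`: codon index vectors `ia`, `ib`
#'   into [codon_space()], `n_codons`, `n_dropped`.
#' @export
build_codon_alignment <- function(ref_cds, outgroup_cds) {
  a <- split_codons(ref_cds)
  b <- split_codons(outgroup_cds)
  if (length(a) != length(b)) stop("build_codon_alignment: unequal lengths")
  ok_chars <- function(x) !grepl("[^ACGT]", x)
  ia <- codon_index(a)
  ib <- codon_index(b)
  stop_a <- ok_chars(a) & is.na(ia)
  stop_b <- ok_chars(b) & is.na(ib)
  if (any(stop_a) || any(stop_b)) {
    internal <- which(stop_a | stop_b)
    internal <- internal[internal < length(a)]
    if (length(internal)) {
      warning("build_codon_alignment: internal stop codon(s) at codon ",
              paste(internal, collapse = ","),
              " dropped (possible pseudogene)")
    }
  }
  keep <- !is.na(ia) & !is.na(ib)
  structure(list(ia = ia[keep], ib = ib[keep],
                 n_codons = sum(keep), n_dropped = sum(!keep)),
            class = "codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat(sprintf("<codon_alignment> %d codons (%d column(s) dropped)\n",
              x$n_codons, x$n_dropped))
  invisible(x)
}

#' F3x4 codon frequencies from a codon alignment
#'
#' Position-specific nucleotide frequencies pooled over both sequences;
#' codon frequencies are products over the three positions, renormalised
#' over the 61 sense codons. Nucleotide frequencies are floored at 1e-6 so
#' short alignments cannot zero out codons.
#'
#' @param aln A `codon_alignment`.
#' @return Numeric vector of 61 codon frequencies summing to 1.
#' @export
f3x4_frequencies <- function(aln) {
  cs <- codon_space()
  obs <- c(cs$codons[aln$ia], cs$codons[aln$ib])
  mat <- do.call(rbind, strsplit(obs, "", fixed = TRUE))
  nts <- c("T", "C", "A", "G")
  posfreq <- sapply(1:3, function(p) {
    f <- table(factor(mat[, p], levels = nts))
    f <- pmax(as.numeric(f) / sum(f), 1e-6)
    f / sum(f)
  })
  rownames(posfreq) <- nts
  cmat <- do.call(rbind, strsplit(cs$codons, "", fixed = TRUE))
  freq <- posfreq[cmat[, 1L], 1L] * posfreq[cmat[, 2L], 2L] *
    posfreq[cmat[, 3L], 3L]
  freq / sum(freq)
}

# ---------------------------------------------------------------------------
# GY94 likelihood
# ---------------------------------------------------------------------------

# Unscaled instantaneous rates (no diagonal): r_ij = pi_j kappa^ts omega^nonsyn
gy94_rates <- function(kappa, omega, freqs) {
  cs <- codon_space()
  R <- matrix(0, 61L, 61L)
  R[cs$single] <- rep(freqs, each = 61L)[cs$single]
  R[cs$single & cs$ts] <- R[cs$single & cs$ts] * kappa
  R[cs$single & cs$nonsyn] <- R[cs$single & cs$nonsyn] * omega
  R
}

# Q scaled to one expected substitution per codon per unit t, plus its
# symmetric eigendecomposition (the chain is reversible w.r.t. freqs).
gy94_decomposition <- function(kappa, omega, freqs) {
  R <- gy94_rates(kappa, omega, freqs)
  diag(R) <- -rowSums(R)
  scale <- -sum(freqs * diag(R))
  if (scale <= 0) stop("gy94: degenerate rate matrix")
  Q <- R / scale
  sq <- sqrt(freqs)
  B <- Q * outer(sq, 1 / sq)          # D^{1/2} Q D^{-1/2}, symmetric
  B <- (B + t(B)) / 2                 # kill round-off asymmetry
  e <- eigen(B, symmetric = TRUE)
  list(values = e$values,
       L1 = e$vectors / sq,           # D^{-1/2} U
       R1 = t(e$vectors * sq),        # U' D^{1/2}
       Q = Q)
}

gy94_P <- function(dec, t) {
  P <- dec$L1 %*% (exp(dec$values * t) * dec$R1)
  pmax(P, 0)
}

#' Transition probability matrix of the GY94 codon model
#'
#' @param t Branch length (expected substitutions per codon).
#' @param kappa Transition/transversion rate ratio.
#' @param omega dN/dS ratio.
#' @param freqs Stationary frequencies over the 61 sense codons.
#' @return 61 x 61 probability matrix `exp(Q t)`.
#' @export
codon_transition_matrix <- function(t, kappa, omega, freqs) {
  P <- gy94_P(gy94_decomposition(kappa, omega, freqs), t)
  sweep(P, 1L, rowSums(P), "/")
}

pair_count_table <- function(aln) {
  # 61x61 observed codon-pair counts
  idx <- (aln$ia - 1L) * 61L + aln$ib
  tab <- tabulate(idx, nbins = 61L * 61L)
  nz <- which(tab > 0L)
  list(i = (nz - 1L) %/% 61L + 1L, j = (nz - 1L) %% 61L + 1L,
       n = tab[nz])
}

loglik_from_P <- function(pc, freqs, P) {
  p <- freqs[pc$i] * P[cbind(pc$i, pc$j)]
  sum(pc$n * log(pmax(p, 1e-300)))
}

#' Log-likelihood of a codon alignment under the GY94 model
#'
#' `lnL = sum over codons of log(pi_{c1} * [exp(Q t)]_{c1,c2})`, i.e. the
#' likelihood of a two-taxon tree rooted (irrelevantly, by reversibility) in
#' the first sequence.
#'
#' @param aln A `codon_alignment` from [build_codon_alignment()].
#' @param t,kappa,omega Model parameters (see [codon_transition_matrix()]).
#' @param freqs Stationary codon frequencies; default F3x4 from the
#'   alignment.
#' @return Log-likelihood (numeric scalar).
#' @export
gy94_loglik <- function(aln, t, kappa, omega, freqs = NULL) {
  if (t < 0 || kappa <= 0 || omega < 0) stop("gy94_loglik: invalid parameters")
  if (is.null(freqs)) freqs <- f3x4_frequencies(aln)
  pc <- pair_count_table(aln)
  dec <- gy94_decomposition(kappa, omega, freqs)
  ll <- loglik_from_P(pc, freqs, gy94_P(dec, t))
  if (!is.finite(ll)) stop("gy94_loglik: non-finite likelihood")
  ll
}

# ---------------------------------------------------------------------------
# ML fitting
# ---------------------------------------------------------------------------

.fit_bounds <- list(t = c(1e-6, 20), kappa = c(0.01, 50), omega = c(1e-4, 20))

# Profile likelihood over t for fixed (kappa, omega): eigendecompose once,
# then 1-D optimisation of t is just matrix reassembly per evaluation.
profile_t <- function(pc, freqs, kappa, omega) {
  dec <- gy94_decomposition(kappa, omega, freqs)
  f <- function(logt) -loglik_from_P(pc, freqs, gy94_P(dec, exp(logt)))
  opt <- optimize(f, interval = log(.fit_bounds$t))
  list(t = exp(opt$minimum), lnL = -opt$objective)
}

#' Fit the GY94 codon model by maximum likelihood
#'
#' Maximises the pairwise log-likelihood over `(t, kappa)` and, unless
#' `fix_omega` is given, over `omega` as well. The branch length is profiled
#' out analytically cheaply (one eigendecomposition per `(kappa, omega)`
#' candidate), and the outer search uses Nelder-Mead on log-parameters from
#' a fixed multi-start grid (`omega` in {0.3, 1, 1.5}; `kappa` = 2), with
#' box constraints `t` in [1e-6, 20], `kappa` in [0.01, 50], `omega` in
#' [1e-4, 20]. Deterministic: the start grid and its ordering are fixed.
#'
#' @param aln A `codon_alignment`.
#' @param fix_omega Optional value at which to fix omega (use `1` for the
#'   neutral model).
#' @param freqs Stationary codon frequencies; `"F3x4"` (default) estimates
#'   them from the alignment, `"equal"` uses 1/61, or pass 61 numbers.
#' @param extra_starts Optional list of additional `c(kappa, omega)` starts.
#' @return List with `t`, `kappa`, `omega`, `lnL`, `freqs`.
#' @export
fit_codon_model <- function(aln, fix_omega = NULL, freqs = "F3x4",
                            extra_starts = NULL) {
  if (is.character(freqs)) {
    freqs <- switch(match.arg(freqs, c("F3x4", "equal")),
                    F3x4 = f3x4_frequencies(aln),
                    equal = rep(1 / 61, 61L))
  }
  pc <- pair_count_table(aln)
  clamp <- function(x, b) pmin(pmax(x, b[1L]), b[2L])
  if (!is.null(fix_omega)) {
    om <- clamp(fix_omega, .fit_bounds$omega)
    f <- function(logk) -profile_t(pc, freqs, exp(logk), om)$lnL
    opt <- optimize(f, interval = log(.fit_bounds$kappa))
    kap <- exp(opt$minimum)
    pr <- profile_t(pc, freqs, kap, om)
    return(list(t = pr$t, kappa = kap, omega = om, lnL = pr$lnL,
                freqs = freqs))
  }
  starts <- list(c(2, 0.3), c(2, 1), c(2, 1.5))
  if (!is.null(extra_starts)) starts <- c(starts, extra_starts)
  obj <- function(par) {
    kap <- clamp(exp(par[1L]), .fit_bounds$kappa)
    om <- clamp(exp(par[2L]), .fit_bounds$omega)
    -profile_t(pc, freqs, kap, om)$lnL
  }
  best <- NULL
  for (s in starts) {
    opt <- optim(log(s), obj, method = "Nelder-Mead",
                 control = list(reltol = 1e-10, maxit = 400L))
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (!is.finite(best$value)) {
    stop("fit_codon_model: optimiser failed from all starts")
  }
  kap <- clamp(exp(best$par[1L]), .fit_bounds$kappa)
  om <- clamp(exp(best$par[2L]), .fit_bounds$omega)
  pr <- profile_t(pc, freqs, kap, om)
  list(t = pr$t, kappa = kap, omega = om, lnL = pr$lnL, freqs = freqs)
}

#' Model-based dN and dS from fitted GY94 parameters
#'
#' Follows the branch-length decomposition convention of ML codon-model
#' software: with Q scaled to one expected substitution per codon per unit
#' `t`, the nonsynonymous flux proportion `rhoN` (and `rhoS = 1 - rhoN`)
#' is computed at the fitted parameters, and the corresponding
#' mutational-opportunity ("site") proportions `fN`, `fS` at the same
#' `kappa` but `omega = 1`. Then `dN = t * rhoN / (3 fN)` and
#' `dS = t * rhoS / (3 fS)`, so that `dN/dS = omega` identically.
#'
#' @param fit Result of [fit_codon_model()].
#' @return List with `dN`, `dS`, `omega`.
#' @export
ml_dnds <- function(fit) {
  cs <- codon_space()
  flux_split <- function(omega) {
    R <- gy94_rates(fit$kappa, omega, fit$freqs)
    flux <- fit$freqs * R            # pi_i r_ij
    totN <- sum(flux[cs$nonsyn & cs$single])
    totS <- sum(flux[!cs$nonsyn & cs$single])
    c(N = totN, S = totS) / (totN + totS)
  }
  rho <- flux_split(fit$omega)
  f <- flux_split(1)
  if (f[["S"]] <= 0) stop("ml_dnds: no synonymous opportunity (dS undefined)")
  list(dN = fit$t * rho[["N"]] / (3 * f[["N"]]),
       dS = fit$t * rho[["S"]] / (3 * f[["S"]]),
       omega = fit$omega)
}

# ---------------------------------------------------------------------------
# Likelihood-ratio test of neutral evolution
# ---------------------------------------------------------------------------

#' 5% chi-square (df = 1) critical value used for the neutrality LRT
#'
#' The one-sided 5% critical value for a chi-square with one degree of
#' freedom, `qchisq(0.90, 1)` = 2.71 to two decimals, the conventional
#' cutoff for the fixed-vs-free omega comparison.
#'
#' @param digits Rounding applied to the returned value (default 2, the
#'   precision at which the cutoff is conventionally quoted).
#' @return Numeric scalar.
#' @export
lrt_cutoff <- function(digits = 2L) {
  round(qchisq(0.90, df = 1L), digits)
}

#' Likelihood-ratio test of neutral evolution (omega = 1 vs free)
#'
#' `LR = 2 (lnML2 - lnML1)` where `lnML1` is the log-likelihood with omega
#' fixed at 1 and `lnML2` with omega free. The gene pair is classed
#' `"Neutral"` when `LR < threshold` (default 2.71, the 5% chi-square
#' df = 1 cutoff): the free-omega model does not fit significantly better,
#' so omega is not distinguishable from 1.
#'
#' @param lnML1 Log-likelihood of the omega = 1 (neutral) model.
#' @param lnML2 Log-likelihood of the free-omega model; must be `>= lnML1`
#'   up to `tol` (the models are nested).
#' @param threshold Significance cutoff on LR.
#' @param tol Numerical tolerance on the nesting constraint; small
#'   violations are clamped to LR = 0, larger ones raise an error
#'   (optimiser-failure signal).
#' @return List with `lnML1`, `lnML2`, `LR`, `classification`.
#' @export
neutrality_lrt <- function(lnML1, lnML2, threshold = lrt_cutoff(), tol = 1e-4) {
  if (lnML2 < lnML1 - tol) {
    stop("neutrality_lrt: lnML2 < lnML1 (free model worse than nested fixed ",
         "model) - optimiser failure")
  }
  LR <- max(2 * (lnML2 - lnML1), 0)
  list(lnML1 = lnML1, lnML2 = lnML2, LR = LR,
       classification = if (LR < threshold) "Neutral" else "Non-neutral")
}

#' Full pairwise neutrality test for one ortholog pair
#'
#' Builds the codon alignment, fits the GY94 model twice (omega fixed at 1,
#' omega free), computes model-based dN/dS and the LRT classification, and
#' attaches the NG86 counting estimates as a cross-check.
#'
#' @param ref_cds,outgroup_cds Equal-length in-frame nucleotide sequences.
#' @param pair_id Label for the pair.
#' @param threshold LR significance cutoff.
#' @param freqs Codon frequency model (see [fit_codon_model()]).
#' @return One-row data.frame: `pair`, `n_codons`, `dS`, `dN`, `omega`,
#'   `lnML1`, `lnML2`, `LR`, `classification`, `ng86_dN`, `ng86_dS`,
#'   `ng86_omega`.
#' @export
neutrality_test <- function(ref_cds, outgroup_cds, pair_id = "pair",
                            threshold = lrt_cutoff(), freqs = "F3x4") {
  aln <- build_codon_alignment(ref_cds, outgroup_cds)
  if (aln$n_codons < 10L) {
    warning("neutrality_test: fewer than 10 codons; estimates unstable")
  }
  fit1 <- fit_codon_model(aln, fix_omega = 1, freqs = freqs)
  fit2 <- fit_codon_model(aln, freqs = freqs,
                          extra_starts = list(c(fit1$kappa, 1)))
  # nested models: never report a free fit below the fixed one
  if (fit2$lnL < fit1$lnL) fit2 <- fit1
  lrt <- neutrality_lrt(fit1$lnL, fit2$lnL, threshold = threshold)
  dd <- ml_dnds(fit2)
  ng <- ng86_dnds(aln)
  data.frame(pair = pair_id, n_codons = aln$n_codons,
             dS = dd$dS, dN = dd$dN, omega = dd$omega,
             lnML1 = fit1$lnL, lnML2 = fit2$lnL, LR = lrt$LR,
             classification = lrt$classification,
             ng86_dN = ng$dN, ng86_dS = ng$dS, ng86_omega = ng$omega,
             stringsAsFactors = FALSE)
}

# ---------------------------------------------------------------------------
# NG86 counting estimator
# ---------------------------------------------------------------------------

# Average syn/nonsyn difference counts over all minimal mutation pathways
# between two codons; paths through stop codons are excluded (equal weights
# over the remaining paths). If every path crosses a stop, all paths are
# used with the stop steps counted as nonsynonymous.
ng86_path_counts <- function(c1, c2) {
  code <- Biostrings::GENETIC_CODE
  pos <- which(strsplit(c1, "")[[1L]] != strsplit(c2, "")[[1L]])
  d <- length(pos)
  if (d == 0L) return(c(sd = 0, nd = 0))
  perms <- if (d == 1L) list(pos) else {
    if (d == 2L) list(pos, rev(pos)) else {
      idx <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                  c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
      lapply(idx, function(o) pos[o])
    }
  }
  walk <- function(order) {
    cur <- c1
    sd <- 0; nd <- 0; blocked <- FALSE
    for (p in order) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      a1 <- code[cur]; a2 <- code[nxt]
      if (a2 == "*" && nxt != c2) blocked <- TRUE
      if (a1 == a2) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(sd = sd, nd = nd, blocked = as.numeric(blocked))
  }
  res <- vapply(perms, walk, numeric(3L))
  open <- res["blocked", ] == 0
  if (any(open)) res <- res[, open, drop = FALSE]
  c(sd = mean(res["sd", ]), nd = mean(res["nd", ]))
}

#' Nei-Gojobori (1986) dN and dS
#'
#' Synonymous and nonsynonymous site counts are averaged over both
#' sequences; differences are counted along all minimal mutation pathways
#' between each codon pair with equal weighting (pathways through stop
#' codons excluded); proportions are corrected for multiple hits with the
#' Jukes-Cantor formula `d = -(3/4) log(1 - (4/3) p)`.
#'
#' @param aln A `codon_alignment`.
#' @return List with `dN`, `dS`, `omega` (NA when `dS` is 0 or a correction
#'   is undefined), `pN`, `pS`, `N_sites`, `S_sites`, and flags
#'   `pn_saturated`, `ps_saturated` (`p >= 3/4`).
#' @export
ng86_dnds <- function(aln) {
  if (aln$n_codons < 1L) stop("ng86_dnds: empty alignment")
  cs <- codon_space()
  s_a <- sum(cs$syn_sites[aln$ia])
  s_b <- sum(cs$syn_sites[aln$ib])
  S_sites <- (s_a + s_b) / 2
  N_sites <- 3 * aln$n_codons - S_sites
  diffs <- aln$ia != aln$ib
  sd <- 0; nd <- 0
  for (k in which(diffs)) {
    pc <- ng86_path_counts(cs$codons[aln$ia[k]], cs$codons[aln$ib[k]])
    sd <- sd + pc[["sd"]]
    nd <- nd + pc[["nd"]]
  }
  pS <- if (S_sites > 0) sd / S_sites else NA_real_
  pN <- nd / N_sites
  jc <- function(p) {
    if (is.na(p) || p >= 3 / 4) return(NA_real_)
    -3 / 4 * log(1 - 4 * p / 3)
  }
  dS <- jc(pS); dN <- jc(pN)
  list(dN = dN, dS = dS,
       omega = if (!is.na(dS) && dS > 0 && !is.na(dN)) dN / dS else NA_real_,
       pN = pN, pS = pS, N_sites = N_sites, S_sites = S_sites,
       pn_saturated = !is.na(pN) && pN >= 3 / 4,
       ps_saturated = !is.na(pS) && pS >= 3 / 4)
}
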