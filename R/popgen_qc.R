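# Population-genetic QC: Hardy-Weinberg equilibrium chi-square tests and
# pairwise linkage disequilibrium (Lewontin's D', r^2) estimated from
# unphased genotypes by EM over the double-heterozygote phase ambiguity.

#' Hardy-Weinberg equilibrium chi-square test
#'
#' Pearson chi-square (1 df) comparing observed genotype counts with those
#' expected under HWE at the allele frequencies estimated from the same
#' counts. Monomorphic input returns chi2 = 0, p = 1.
#'
#' @param n_AA,n_Aa,n_aa nonnegative genotype counts.
#' @return list of class `hwe_result`: counts, allele frequency `p_hat`,
#'   `chi2`, `df` (1) and `p_value`.
#' @examples
#' hwe_chi2(30, 40, 30)  # chi2 = 4, p ~ 0.0455
#' @export
hwe_chi2 <- function(n_AA, n_Aa, n_aa) {
  counts <- c(n_AA, n_Aa, n_aa)
  if (any(is.na(counts)) || any(counts < 0)) stop("genotype counts must be nonnegative")
  n <- sum(counts)
  if (n == 0) stop("no genotypes")
  p <- (2 * n_AA + n_Aa) / (2 * n)
  if (p == 0 || p == 1) {
    chi2 <- 0; pv <- 1
  } else {
    expd <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
    chi2 <- sum((counts - expd)^2 / expd)
    pv <- pchisq(chi2, df = 1, lower.tail = FALSE)
  }
  structure(list(n_AA = n_AA, n_Aa = n_Aa, n_aa = n_aa, p_hat = p,
                 chi2 = chi2, df = 1L, p_value = pv),
            class = "hwe_result")
}

#' @export
print.hwe_result <- function(x, ...) {
  cat(sprintf("HWE chi-square: counts (%g, %g, %g), chi2 = %.4g, p = %.4g\n",
              x$n_AA, x$n_Aa, x$n_aa, x$chi2, x$p_value))
  invisible(x)
}

#' Per-SNP HWE tests for a cohort
#'
#' By default tested among controls only, the conventional QC stratum for a
#' case-control study (deviation among cases can be disease-driven).
#'
#' @param gm a `geno_matrix`.
#' @param ph a `phenotype`; may be omitted when `stratum = "pooled"`.
#' @param stratum `"control"` (default), `"case"` or `"pooled"`.
#' @return data.frame with one row per SNP: genotype counts, chi2, p_value.
#' @export
hwe_scan <- function(gm, ph = NULL, stratum = c("control", "case", "pooled")) {
  stratum <- match.arg(stratum)
  if (stratum != "pooled") {
    stopifnot(!is.null(ph))
    gm <- split_by_status(gm, ph)[[stratum]]
  }
  rows <- lapply(snp_ids(gm), function(s) {
    d <- gm$dosage[, s]
    r <- hwe_chi2(sum(d == 2L, na.rm = TRUE), sum(d == 1L, na.rm = TRUE),
                  sum(d == 0L, na.rm = TRUE))
    data.frame(snp_id = s, n_AA = r$n_AA, n_Aa = r$n_Aa, n_aa = r$n_aa,
               chi2 = r$chi2, p_value = r$p_value, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Pairwise LD (D, D', r2) by EM from unphased genotypes
#'
#' Maximizes the multinomial likelihood of the 3x3 genotype cross-table over
#' the two-locus haplotype frequencies, resolving the double-heterozygote
#' phase ambiguity by EM (phase split from the current frequency estimates
#' each E-step). Initialization at linkage equilibrium; convergence when the
#' largest haplotype-frequency change falls below `tol` (default 1e-10) or
#' after `max_iter` iterations. Then D = pAB - pA pB, D' = D/Dmax with
#' Dmax = min(pA qB, qA pB) for D > 0 and min(pA pB, qA qB) for D < 0, and
#' r2 = D^2 / (pA qA pB qB). If Dmax = 0 (an allele frequency at the
#' boundary) D' is reported as 0 with a warning flag.
#'
#' @param dosage_a,dosage_b integer dosage vectors (0/1/2, NA = missing) for
#'   the two SNPs; pairs with a missing value at either SNP are dropped.
#' @param snp_a,snp_b optional SNP labels carried into the result.
#' @param max_iter,tol EM controls.
#' @return list of class `ld_result`: `D`, `d_prime`, `r2`, haplotype
#'   frequencies `hap`, `em_iterations`, final `loglik`, `loglik_trace`,
#'   `boundary` flag.
#' @export
ld_em <- function(dosage_a, dosage_b, snp_a = "A", snp_b = "B",
                  max_iter = 1000L, tol = 1e-10) {
  keep <- !is.na(dosage_a) & !is.na(dosage_b)
  a <- dosage_a[keep]; b <- dosage_b[keep]
  if (length(a) < 2L) stop("fewer than 2 jointly observed samples")
  if (length(unique(a)) < 2L || length(unique(b)) < 2L)
    stop("LD undefined: monomorphic SNP among jointly observed samples")

  n <- matrix(0, 3, 3)
  for (i in 0:2) for (j in 0:2) n[i + 1, j + 1] <- sum(a == i & b == j)
  N <- sum(n)

  # haplotype counts fixed by genotype except for the double heterozygote
  kAB <- 2 * n[3, 3] + n[3, 2] + n[2, 3]
  kAb <- 2 * n[3, 1] + n[3, 2] + n[2, 1]
  kaB <- 2 * n[1, 3] + n[2, 3] + n[1, 2]
  kab <- 2 * n[1, 1] + n[2, 1] + n[1, 2]
  nDH <- n[2, 2]

  pA <- (kAB + kAb + nDH) / (2 * N)
  pB <- (kAB + kaB + nDH) / (2 * N)
  h <- c(AB = pA * pB, Ab = pA * (1 - pB), aB = (1 - pA) * pB,
         ab = (1 - pA) * (1 - pB))

  cell_probs <- function(h) {
    # P(genotype cell) under random union of haplotypes
    hap_dosA <- c(1, 1, 0, 0); hap_dosB <- c(1, 0, 1, 0)
    P <- matrix(0, 3, 3)
    for (x in 1:4) for (y in 1:4) {
      i <- hap_dosA[x] + hap_dosA[y]; j <- hap_dosB[x] + hap_dosB[y]
      P[i + 1, j + 1] <- P[i + 1, j + 1] + h[x] * h[y]
    }
    P
  }
  obs_loglik <- function(h) {
    P <- cell_probs(h)
    sum(n[n > 0] * log(P[n > 0]))
  }

  trace <- obs_loglik(h)
  iters <- 0L
  for (it in seq_len(max_iter)) {
    iters <- it
    denom <- h[["AB"]] * h[["ab"]] + h[["Ab"]] * h[["aB"]]
    rho <- if (denom > 0) (h[["AB"]] * h[["ab"]]) / denom else 0.5
    h_new <- c(AB = (kAB + rho * nDH) / (2 * N),
               Ab = (kAb + (1 - rho) * nDH) / (2 * N),
               aB = (kaB + (1 - rho) * nDH) / (2 * N),
               ab = (kab + rho * nDH) / (2 * N))
    delta <- max(abs(h_new - h))
    h <- h_new
    trace <- c(trace, obs_loglik(h))
    if (delta < tol) break
  }

  pA <- h[["AB"]] + h[["Ab"]]; pB <- h[["AB"]] + h[["aB"]]
  qA <- 1 - pA; qB <- 1 - pB
  D <- h[["AB"]] - pA * pB
  dmax <- if (D >= 0) min(pA * qB, qA * pB) else min(pA * pB, qA * qB)
  boundary <- dmax <= .Machine$double.eps
  d_prime <- if (boundary) {
    warning("Dmax = 0 (allele frequency at boundary); D' reported as 0")
    0
  } else unname(D / dmax)
  r2 <- if (pA * qA * pB * qB > 0) unname(D^2 / (pA * qA * pB * qB)) else 0

  structure(list(snp_a = snp_a, snp_b = snp_b, D = D, d_prime = d_prime,
                 r2 = r2, hap = h, em_iterations = iters,
                 loglik = trace[length(trace)], loglik_trace = unname(trace),
                 boundary = boundary, n_pairs = N),
            class = "ld_result")
}

#' @export
print.ld_result <- function(x, ...) {
  cat(sprintf("LD %s ~ %s: D = %.4g, D' = %.4g, r2 = %.4g (EM, %d iter)\n",
              x$snp_a, x$snp_b, x$D, x$d_prime, x$r2, x$em_iterations))
  invisible(x)
}

#' Pairwise LD scan over a cohort
#'
#' Computes [ld_em()] for every SNP pair (or a supplied subset), by default
#' among controls only, matching the QC role; monomorphic SNPs are skipped
#' with a warning.
#'
#' @param gm a `geno_matrix`.
#' @param ph a `phenotype`; may be omitted when `stratum = "pooled"`.
#' @param stratum `"control"` (default), `"case"` or `"pooled"`.
#' @param pairs optional 2-column matrix/data.frame of SNP id pairs.
#' @return data.frame: snp_a, snp_b, D, d_prime, r2, em_iterations.
#' @export
ld_scan <- function(gm, ph = NULL, stratum = c("control", "case", "pooled"),
                    pairs = NULL) {
  stratum <- match.arg(stratum)
  if (stratum != "pooled") {
    stopifnot(!is.null(ph))
    gm <- split_by_status(gm, ph)[[stratum]]
  }
  snps <- snp_ids(gm)
  if (is.null(pairs)) {
    if (length(snps) < 2L) stop("need at least two SNPs")
    pairs <- t(utils::combn(snps, 2))
  }
  pairs <- as.matrix(pairs)
  rows <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    res <- tryCatch(
      ld_em(gm$dosage[, pairs[i, 1]], gm$dosage[, pairs[i, 2]],
            snp_a = pairs[i, 1], snp_b = pairs[i, 2]),
      error = function(e) NULL)
    if (is.null(res)) {
      warning("skipping pair ", pairs[i, 1], " ~ ", pairs[i, 2],
              " (monomorphic or insufficient data)")
      next
    }
    rows[[i]] <- data.frame(snp_a = res$snp_a, snp_b = res$snp_b, D = res$D,
                            d_prime = res$d_prime, r2 = res$r2,
                            em_iterations = res$em_iterations,
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
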