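# Retrospectively ascertained case-control cohort simulator. Individuals are
# drawn from a source population in Hardy-Weinberg equilibrium (optionally
# with pairwise LD), disease arises under a prospective log-additive logistic
# model whose intercept is calibrated to a target prevalence, and sampling
# continues until the case and control quotas are filled (rejection
# sampling), emulating a case-control study design.

#' Configure a synthetic case-control cohort
#'
#' @param variants a `variant_panel` (or coercible); `control_raf` is used as
#'   the population risk-allele frequency.
#' @param per_allele_or positive per-allele odds ratio per variant (recycled);
#'   defaults to the panel's `or_univariate` column when present, else 1.
#' @param prevalence population disease probability in (0, 1); default 0.005,
#'   a Crohn's-disease-like rare-disease regime in which odds ratios
#'   approximate relative risks.
#' @param n_case,n_control numbers of cases and controls to retain.
#' @param ld_pairs optional data.frame with columns `snp_a`, `snp_b`,
#'   `d_prime` requesting pairwise LD between two panel SNPs (each SNP in at
#'   most one pair); remaining SNPs are independent.
#' @param seed integer master seed; identical configuration and seed give
#'   identical cohorts.
#' @param max_draw_factor sampling cap as a multiple of the expected number
#'   of population draws needed to fill the quotas.
#' @return list of class `cohort_config`.
#' @export
cohort_config <- function(variants, per_allele_or = NULL, prevalence = 0.005,
                          n_case, n_control, ld_pairs = NULL, seed = 1L,
                          max_draw_factor = 20) {
  variants <- as_variant_panel(variants)
  if (is.null(per_allele_or)) {
    per_allele_or <- if ("or_univariate" %in% names(variants))
      variants$or_univariate else rep(1, nrow(variants))
  }
  per_allele_or <- rep_len(as.numeric(per_allele_or), nrow(variants))
  if (any(!is.finite(per_allele_or)) || any(per_allele_or <= 0))
    stop("per_allele_or must be positive and finite")
  if (!(prevalence > 0 && prevalence < 1)) stop("prevalence must lie in (0, 1)")
  if (any(is.na(variants$control_raf)))
    stop("every variant needs a control_raf (population frequency)")
  if (!is.null(ld_pairs)) {
    stopifnot(all(c("snp_a", "snp_b", "d_prime") %in% names(ld_pairs)))
    mem <- c(ld_pairs$snp_a, ld_pairs$snp_b)
    if (anyDuplicated(mem)) stop("each SNP may appear in at most one LD pair")
    if (!all(mem %in% variants$snp_id))
      stop("LD pair SNP(s) not in panel: ",
           paste(setdiff(mem, variants$snp_id), collapse = ", "))
  }
  structure(list(variants = variants, per_allele_or = per_allele_or,
                 prevalence = prevalence, n_case = as.integer(n_case),
                 n_control = as.integer(n_control), ld_pairs = ld_pairs,
                 seed = as.integer(seed), max_draw_factor = max_draw_factor),
            class = "cohort_config")
}

#' Two-locus haplotype frequencies at a target D'
#'
#' Builds the four haplotype frequencies for two loci with risk-allele
#' frequencies `raf_a`, `raf_b` and Lewontin's normalized disequilibrium
#' `d_prime`: D = d_prime * Dmax with Dmax = min(pA(1-pB), (1-pA)pB) for
#' nonnegative d_prime (mirrored for negative), then pAB = pA pB + D etc.
#'
#' @param raf_a,raf_b allele frequencies in (0, 1).
#' @param d_prime target normalized disequilibrium in \[-1, 1\].
#' @return named numeric of class `haplotype_pair`
#'   (`freq_AB`, `freq_Ab`, `freq_aB`, `freq_ab`).
#' @export
make_haplotype_pair <- function(raf_a, raf_b, d_prime) {
  stopifnot(raf_a > 0, raf_a < 1, raf_b > 0, raf_b < 1,
            abs(d_prime) <= 1)
  qa <- 1 - raf_a; qb <- 1 - raf_b
  dmax <- if (d_prime >= 0) min(raf_a * qb, qa * raf_b)
          else              min(raf_a * raf_b, qa * qb)
  D <- d_prime * dmax
  h <- c(freq_AB = raf_a * raf_b + D,
         freq_Ab = raf_a * qb    - D,
         freq_aB = qa    * raf_b - D,
         freq_ab = qa    * qb    + D)
  if (any(h < -1e-12))
    stop("invalid d_prime/frequency combination: negative haplotype frequency")
  h <- pmax(h, 0)
  structure(h / sum(h), class = "haplotype_pair")
}

# ---- distribution of the genetic linear predictor --------------------------

# Independent blocks of the genotype distribution: one per unpaired SNP
# (3 support points, HWE probabilities) and one per LD pair (9 support
# points from two iid haplotype draws).
lp_blocks <- function(config) {
  v <- config$variants
  beta <- log(config$per_allele_or)
  paired <- character(0)
  blocks <- list()
  if (!is.null(config$ld_pairs)) {
    for (i in seq_len(nrow(config$ld_pairs))) {
      a <- config$ld_pairs$snp_a[i]; b <- config$ld_pairs$snp_b[i]
      ja <- match(a, v$snp_id); jb <- match(b, v$snp_id)
      h <- make_haplotype_pair(v$control_raf[ja], v$control_raf[jb],
                               config$ld_pairs$d_prime[i])
      # ordered pairs of haplotypes -> joint dosage distribution
      hapA <- c(1, 1, 0, 0); hapB <- c(1, 0, 1, 0)
      probs <- as.numeric(outer(h, h))
      dosA <- as.integer(outer(hapA, hapA, "+"))
      dosB <- as.integer(outer(hapB, hapB, "+"))
      vals <- beta[ja] * dosA + beta[jb] * dosB
      blocks[[length(blocks) + 1L]] <- list(
        type = "pair", snps = c(ja, jb), hap = h,
        values = vals, probs = probs, dosA = dosA, dosB = dosB)
      paired <- c(paired, a, b)
    }
  }
  for (j in seq_len(nrow(v))) {
    if (v$snp_id[j] %in% paired) next
    p <- v$control_raf[j]
    blocks[[length(blocks) + 1L]] <- list(
      type = "single", snps = j,
      values = beta[j] * (0:2),
      probs = c((1 - p)^2, 2 * p * (1 - p), p^2))
  }
  blocks
}

# Distribution of S = sum_i beta_i * dosage_i over the population genotype
# distribution. Exact enumeration while the joint support stays small; for
# larger panels a fine-grid convolution (step `h`) with linear probability
# splitting, whose error in E[logistic(.)] is second order in h.
lp_distribution <- function(blocks, exact_cap = 2e5, h = 1e-3) {
  sizes <- vapply(blocks, function(b) length(b$values), numeric(1))
  if (prod(sizes) <= exact_cap) {
    vals <- 0; probs <- 1
    for (b in blocks) {
      vals <- as.numeric(outer(vals, b$values, "+"))
      probs <- as.numeric(outer(probs, b$probs, "*"))
    }
    return(list(values = vals, probs = probs))
  }
  pmf <- 1; origin <- 0
  for (b in blocks) {
    vmin <- min(b$values)
    s <- (b$values - vmin) / h
    n_new <- length(pmf) + as.integer(ceiling(max(s))) + 1L
    out <- numeric(n_new)
    idx <- seq_along(pmf)
    for (k in seq_along(s)) {
      f <- floor(s[k]); w <- s[k] - f
      out[idx + f] <- out[idx + f] + b$probs[k] * (1 - w) * pmf
      if (w > 0) out[idx + f + 1L] <- out[idx + f + 1L] + b$probs[k] * w * pmf
    }
    pmf <- out; origin <- origin + vmin
  }
  list(values = origin + (seq_along(pmf) - 1) * h, probs = pmf)
}

#' Calibrate the logistic intercept to a target prevalence
#'
#' Finds `b0` such that the expectation, over the population genotype
#' distribution, of `logistic(b0 + sum(log(OR_i) * dosage_i))` equals the
#' configured prevalence, by bisection (residual below 1e-8).
#'
#' @param config a `cohort_config`.
#' @return the intercept (log-odds scale).
#' @examples
#' cfg <- cohort_config(variant_panel("x", control_raf = 0.5),
#'                      per_allele_or = 1, prevalence = 0.2,
#'                      n_case = 10, n_control = 10)
#' calibrate_intercept(cfg)  # log(0.2/0.8)
#' @export
calibrate_intercept <- function(config) {
  dist <- lp_distribution(lp_blocks(config))
  f <- function(b0) sum(dist$probs * plogis(b0 + dist$values)) - config$prevalence
  lo <- stats::qlogis(config$prevalence) - max(dist$values) - 1
  hi <- stats::qlogis(config$prevalence) - min(dist$values) + 1
  for (w in 1:30) {
    if (f(lo) < 0 && f(hi) > 0) break
    lo <- lo - 2^w; hi <- hi + 2^w
  }
  if (!(f(lo) < 0 && f(hi) > 0))
    stop("could not bracket the prevalence-calibrating intercept")
  for (it in 1:200) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (abs(fm) <= 1e-8 || (hi - lo) < 1e-12) return(mid)
    if (fm > 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

#' Genotype distribution within a disease stratum (single SNP)
#'
#' Analytic Bayes inversion of the prospective logistic model:
#' P(dosage | status) is proportional to P(status | dosage) * P(dosage) with
#' P(dosage) the Hardy-Weinberg population distribution. Serves as an
#' independent oracle for the rejection-sampling simulator.
#'
#' @param raf population risk-allele frequency.
#' @param or per-allele odds ratio.
#' @param intercept logistic intercept (see [calibrate_intercept()]).
#' @param stratum `"case"` or `"control"`.
#' @return probabilities of dosage 0, 1, 2 within the stratum (sums to 1).
#' @export
expected_genotype_freq_in_stratum <- function(raf, or, intercept,
                                              stratum = c("case", "control")) {
  stratum <- match.arg(stratum)
  stopifnot(raf >= 0, raf <= 1, or > 0)
  g <- c((1 - raf)^2, 2 * raf * (1 - raf), raf^2)
  p_case <- plogis(intercept + log(or) * (0:2))
  w <- if (stratum == "case") g * p_case else g * (1 - p_case)
  w / sum(w)
}

#' Simulate a case-control cohort
#'
#' Draws individuals from the configured source population (HWE genotypes;
#' LD pairs as two independent haplotypes), assigns disease as
#' Bernoulli(logistic(b0 + sum(log(OR) * dosage))) with the intercept
#' calibrated to the target prevalence, and retains individuals in draw
#' order until the case and control quotas are filled.
#'
#' @param config a `cohort_config`.
#' @return list with `genotypes` (`geno_matrix`), `phenotypes` (`phenotype`)
#'   and `sim_info` (intercept, total population draws, cases among them,
#'   realized prevalence before quota truncation).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  v <- config$variants
  k <- nrow(v)
  beta <- log(config$per_allele_or)
  b0 <- calibrate_intercept(config)
  blocks <- lp_blocks(config)

  expected_draws <- max(config$n_case / config$prevalence,
                        config$n_control / (1 - config$prevalence))
  cap <- ceiling(config$max_draw_factor * expected_draws)
  batch <- min(as.integer(ceiling(1.1 * expected_draws) + 100), cap)
  if (batch < 1L)
    stop("max_draw_factor too small: sampling cap below one draw")

  set.seed(config$seed)
  need_case <- config$n_case; need_control <- config$n_control
  kept_dos <- vector("list", 0); kept_status <- vector("list", 0)
  total_drawn <- 0; cases_drawn <- 0

  while (need_case > 0L || need_control > 0L) {
    if (total_drawn >= cap)
      stop(sprintf(paste0("sampling cap reached after %d draws (prevalence ",
                          "%.4g too extreme for quotas %d/%d)"),
                   total_drawn, config$prevalence,
                   config$n_case, config$n_control))
    dos <- matrix(0L, nrow = batch, ncol = k,
                  dimnames = list(NULL, v$snp_id))
    for (b in blocks) {
      if (b$type == "single") {
        dos[, b$snps] <- rbinom(batch, 2L, v$control_raf[b$snps])
      } else {
        i1 <- sample.int(4L, batch, replace = TRUE, prob = b$hap)
        i2 <- sample.int(4L, batch, replace = TRUE, prob = b$hap)
        dos[, b$snps[1]] <- as.integer(i1 <= 2L) + as.integer(i2 <= 2L)
        dos[, b$snps[2]] <- as.integer(i1 %% 2L == 1L) +
                            as.integer(i2 %% 2L == 1L)
      }
    }
    pr <- plogis(b0 + as.numeric(dos %*% beta))
    y <- rbinom(batch, 1L, pr)
    total_drawn <- total_drawn + batch
    cases_drawn <- cases_drawn + sum(y)

    take_case <- utils::head(which(y == 1L), need_case)
    take_control <- utils::head(which(y == 0L), need_control)
    take <- sort(c(take_case, take_control))
    if (length(take)) {
      kept_dos[[length(kept_dos) + 1L]] <- dos[take, , drop = FALSE]
      kept_status[[length(kept_status) + 1L]] <- y[take]
      need_case <- need_case - length(take_case)
      need_control <- need_control - length(take_control)
    }
  }
  dosage <- do.call(rbind, kept_dos)
  status <- unlist(kept_status)
  rownames(dosage) <- sprintf("S%05d", seq_len(nrow(dosage)))
  list(genotypes = genotype_matrix(dosage, v),
       phenotypes = phenotype_vector(rownames(dosage), status),
       sim_info = list(intercept = b0, total_drawn = total_drawn,
                       cases_drawn = cases_drawn,
                       realized_prevalence = cases_drawn / total_drawn))
}

#' Simulate the reference 22-SNP cohort
#'
#' Convenience wrapper: builds a [cohort_config()] from the packaged
#' reference panel (control risk-allele frequencies as population
#' frequencies, univariate allelic odds ratios as per-allele effects) and
#' emits a 22-SNP cohort of 369 cases and 503 controls.
#'
#' @param seed integer master seed.
#' @param prevalence population prevalence (default 0.005).
#' @param n_case,n_control quota sizes (defaults 369 / 503).
#' @param ld_pairs optional LD pair specification, see [cohort_config()].
#' @return as [simulate_cohort()].
#' @export
simulate_reference_cohort <- function(seed = 1L, prevalence = 0.005,
                                      n_case = 369L, n_control = 503L,
                                      ld_pairs = NULL) {
  panel <- reference_panel()
  cfg <- cohort_config(panel, per_allele_or = panel$or_univariate,
                       prevalence = prevalence, n_case = n_case,
                       n_control = n_control, ld_pairs = ld_pairs,
                       seed = seed)
  simulate_cohort(cfg)
}
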