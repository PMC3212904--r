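# Case-control association statistics: allelic / carriage / compound 2x2
# odds ratios with Wald intervals and p-values, multivariate logistic
# regression by IRLS with step-halving, and analytic power for the allelic
# test. Zero cells receive the Haldane-Anscombe 0.5 correction (all four
# cells), flagged in the result.

#' Allelic 2x2 odds-ratio test with Wald interval
#'
#' OR = ad/bc (0.5 added to every cell iff any cell is zero, flagged),
#' SE(log OR) = sqrt(1/a + 1/b + 1/c + 1/d), 95% Wald CI
#' exp(log OR +/- z * SE), two-sided normal p-value for log OR / SE.
#'
#' @param tab a [two_by_two()] (a exposed cases, b unexposed cases, c exposed
#'   controls, d unexposed controls).
#' @param conf_level confidence level (default 0.95).
#' @param label optional result label.
#' @param coding tag recording how exposure was coded.
#' @return list of class `assoc_result`: `or`, `ci_low`, `ci_high`,
#'   `p_value`, `haldane` flag, the table, `coding`, `label`.
#' @examples
#' allelic_test(two_by_two(27, 342, 3, 500))  # OR 13.16 (3.96-43.72)
#' @export
allelic_test <- function(tab, conf_level = 0.95, label = NA_character_,
                         coding = "allelic") {
  stopifnot(inherits(tab, "two_by_two"))
  a <- tab$a; b <- tab$b; c <- tab$c; d <- tab$d
  if (a + b == 0 || c + d == 0)
    stop("empty case or control margin: odds ratio undefined")
  haldane <- any(c(a, b, c, d) == 0)
  if (haldane) { a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5 }
  lor <- log((a * d) / (b * c))
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  z <- qnorm(1 - (1 - conf_level) / 2)
  p <- 2 * pnorm(-abs(lor / se))
  structure(list(label = label, or = exp(lor), ci_low = exp(lor - z * se),
                 ci_high = exp(lor + z * se), p_value = p, se_log_or = se,
                 haldane = haldane, coding = coding, table = tab),
            class = "assoc_result")
}

#' @export
print.assoc_result <- function(x, ...) {
  cat(sprintf("%s%sOR = %.3g (%.3g-%.3g), p = %.3g%s\n",
              if (is.na(x$label)) "" else paste0(x$label, ": "),
              if (x$coding == "allelic") "" else paste0("[", x$coding, "] "),
              x$or, x$ci_low, x$ci_high, x$p_value,
              if (isTRUE(x$haldane)) " [Haldane-corrected]" else ""))
  invisible(x)
}

#' @export
as.data.frame.assoc_result <- function(x, ...) {
  data.frame(label = x$label, coding = x$coding, or = x$or,
             ci_low = x$ci_low, ci_high = x$ci_high, p_value = x$p_value,
             haldane = x$haldane, stringsAsFactors = FALSE)
}

# allele-count 2x2 for one SNP (alleles as observations, 2n denominators)
snp_allele_table <- function(gm, ph, snp_id) {
  sp <- split_by_status(gm, ph)
  dca <- sp$case$dosage[, snp_id]; dco <- sp$control$dosage[, snp_id]
  a <- sum(dca, na.rm = TRUE)
  b <- 2 * sum(!is.na(dca)) - a
  c <- sum(dco, na.rm = TRUE)
  d <- 2 * sum(!is.na(dco)) - c
  two_by_two(a, b, c, d)
}

#' Per-SNP allelic association test
#'
#' Treats alleles as independent observations (2n denominators).
#'
#' @param gm a `geno_matrix`.
#' @param ph a `phenotype`.
#' @param snp_id SNP identifier.
#' @return an `assoc_result`.
#' @export
allelic_test_snp <- function(gm, ph, snp_id) {
  allelic_test(snp_allele_table(gm, ph, snp_id), label = snp_id)
}

# exposure-indicator 2x2 over samples, excluding samples missing at every
# listed SNP (logged)
exposure_table <- function(gm, ph, snp_ids, expose_fn) {
  stopifnot(all(snp_ids %in% colnames(gm$dosage)))
  d <- gm$dosage[, snp_ids, drop = FALSE]
  all_missing <- rowSums(!is.na(d)) == 0L
  if (any(all_missing))
    message(sum(all_missing), " sample(s) missing at all listed SNPs excluded")
  d <- d[!all_missing, , drop = FALSE]
  exposed <- expose_fn(d)
  st <- ph$status[match(rownames(d), ph$sample_id)]
  two_by_two(sum(exposed & st == 1L), sum(!exposed & st == 1L),
             sum(exposed & st == 0L), sum(!exposed & st == 0L))
}

#' Carriage odds ratio (at least one risk allele across listed SNPs)
#'
#' @param gm a `geno_matrix`.
#' @param ph a `phenotype`.
#' @param snp_ids SNPs defining the carriage set.
#' @param label optional result label.
#' @return an `assoc_result` with coding `"carriage"`.
#' @export
carriage_test <- function(gm, ph, snp_ids, label = "carriage") {
  tab <- exposure_table(gm, ph, snp_ids,
                        function(d) rowSums(d >= 1L, na.rm = TRUE) > 0L)
  allelic_test(tab, label = label, coding = "carriage")
}

#' Compound heterozygous/homozygous odds ratio (>= 2 risk alleles)
#'
#' Exposure is a total of two or more risk alleles across the listed SNPs
#' (homozygote at one SNP or heterozygote at two).
#'
#' @inheritParams carriage_test
#' @return an `assoc_result` with coding `"compound"`.
#' @export
compound_test <- function(gm, ph, snp_ids, label = "compound het/hom") {
  tab <- exposure_table(gm, ph, snp_ids,
                        function(d) rowSums(d, na.rm = TRUE) >= 2L)
  allelic_test(tab, label = label, coding = "compound")
}

#' Table of univariate per-SNP association results
#'
#' @param gm a `geno_matrix`.
#' @param ph a `phenotype`.
#' @return data.frame: snp_id, gene, control/case risk-allele frequencies,
#'   allelic OR, CI, p-value.
#' @export
univariate_scan <- function(gm, ph) {
  sp <- split_by_status(gm, ph)
  rows <- lapply(snp_ids(gm), function(s) {
    r <- allelic_test_snp(gm, ph, s)
    data.frame(snp_id = s,
               gene = gm$variants$gene[match(s, gm$variants$snp_id)],
               control_raf = allele_frequency(sp$control, s),
               case_raf = allele_frequency(sp$case, s),
               or = r$or, ci_low = r$ci_low, ci_high = r$ci_high,
               p_value = r$p_value, haldane = r$haldane,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# ---- logistic regression by IRLS -------------------------------------------

#' Logistic regression by iteratively reweighted least squares
#'
#' Newton-Raphson/IRLS maximization of the Bernoulli log-likelihood with
#' step-halving (the log-likelihood never decreases between iterations).
#' Wald standard errors come from the inverse observed information.
#' Convergence requires every score-equation residual below `tol`. Perfect
#' separation (a coefficient walking beyond +/-15 while the likelihood still
#' climbs) is flagged: the fit is returned with `converged = FALSE` and
#' `separated = TRUE` rather than an error, mirroring the "ND" convention
#' for inestimable genotype cells.
#'
#' @param design numeric matrix of covariates (no intercept column; one is
#'   prepended). Must be full rank.
#' @param outcome 0/1 vector.
#' @param max_iter maximum IRLS iterations (default 100).
#' @param tol score convergence tolerance (default 1e-8).
#' @return list of class `logistic_fit`: `coefficients`, `se`, `vcov`,
#'   `converged`, `separated`, `iterations`, `loglik`, `loglik_trace`,
#'   `fitted`.
#' @export
logistic_fit <- function(design, outcome, max_iter = 100L, tol = 1e-8) {
  X <- cbind(`(Intercept)` = 1, as.matrix(design))
  y <- as.numeric(outcome)
  stopifnot(length(y) == nrow(X), all(y %in% c(0, 1)))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  beta <- numeric(ncol(X)); names(beta) <- colnames(X)
  loglik <- function(b) {
    eta <- as.numeric(X %*% b)
    sum(y * eta - log1p(exp(eta)))
  }
  ll <- loglik(beta); trace <- ll
  converged <- FALSE; separated <- FALSE; iters <- 0L
  for (it in seq_len(max_iter)) {
    iters <- it
    eta <- as.numeric(X %*% beta)
    mu <- plogis(eta)
    W <- mu * (1 - mu)
    score <- as.numeric(crossprod(X, y - mu))
    if (max(abs(score)) < tol) { converged <- TRUE; break }
    info <- crossprod(X, X * W)
    step <- tryCatch(solve(info, score), error = function(e) NULL)
    if (is.null(step)) break
    # step-halving: never accept a likelihood decrease
    lambda <- 1
    repeat {
      cand <- beta + lambda * step
      ll_new <- loglik(cand)
      if (ll_new >= ll - 1e-12 || lambda < 1e-10) break
      lambda <- lambda / 2
    }
    beta <- cand; ll <- ll_new
    trace <- c(trace, ll)
    if (any(abs(beta) > 15)) { separated <- TRUE; break }
  }
  # final score check at the accepted coefficients
  mu <- plogis(as.numeric(X %*% beta))
  score <- as.numeric(crossprod(X, y - mu))
  if (max(abs(score)) < tol && !separated) converged <- TRUE
  info <- crossprod(X, X * (mu * (1 - mu)))
  vc <- tryCatch(solve(info), error = function(e) matrix(NA_real_, ncol(X), ncol(X)))
  se <- sqrt(diag(vc)); names(se) <- colnames(X)
  if (separated)
    warning("possible perfect separation: |coefficient| > 15; fit flagged ",
            "not converged")
  structure(list(coefficients = beta, se = se, vcov = vc,
                 converged = converged, separated = separated,
                 iterations = iters, loglik = ll, loglik_trace = trace,
                 fitted = mu),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("<logistic_fit> %d terms, loglik %.4f, %s in %d iterations%s\n",
              length(x$coefficients), x$loglik,
              if (x$converged) "converged" else "NOT converged", x$iterations,
              if (x$separated) " [separation suspected]" else ""))
  print(data.frame(coef = x$coefficients, se = x$se,
                   or = exp(x$coefficients)))
  invisible(x)
}

# design matrices from a genotype matrix
genotype_design <- function(gm, snps, coding = c("log_additive", "genotype")) {
  coding <- match.arg(coding)
  d <- gm$dosage[, snps, drop = FALSE]
  if (coding == "log_additive") {
    storage.mode(d) <- "double"
    return(d)
  }
  cols <- lapply(snps, function(s) {
    m <- cbind(as.numeric(d[, s] == 1L), as.numeric(d[, s] == 2L))
    colnames(m) <- paste0(s, c("_1copy", "_2copy"))
    m
  })
  do.call(cbind, cols)
}

#' Multivariate logistic model over a SNP panel
#'
#' Fits the joint effect of the panel SNPs on case status. Codings:
#' `"log_additive"` (one linear dosage term per SNP; the per-allele OR) or
#' `"genotype"` (indicator pair per SNP: 1 copy, 2 copies vs none). Samples
#' with a missing genotype at any used SNP are dropped with a message.
#' Inestimable terms (separation) are reported with `estimable = FALSE`.
#'
#' @param gm a `geno_matrix`.
#' @param ph a `phenotype`.
#' @param snps SNP ids (default: all SNPs of `gm`).
#' @param coding `"log_additive"` or `"genotype"`.
#' @return list with `fit` (a `logistic_fit`) and `table` (per-term OR, CI,
#'   p, estimable flag; intercept excluded).
#' @export
multivariate_fit <- function(gm, ph, snps = snp_ids(gm),
                             coding = c("log_additive", "genotype")) {
  coding <- match.arg(coding)
  X <- genotype_design(gm, snps, coding)
  cc <- complete.cases(X)
  if (any(!cc)) message(sum(!cc), " sample(s) with missing genotypes dropped")
  X <- X[cc, , drop = FALSE]
  st <- ph$status[match(rownames(gm$dosage)[cc], ph$sample_id)]
  # degenerate genotype cells (empty or aliased, e.g. no 2-copy carriers or
  # no non-carriers) make terms inestimable; drop and flag rather than fail
  drop_cols <- apply(X, 2, function(col) length(unique(col)) == 1L)
  qrX <- qr(cbind(1, X[, !drop_cols, drop = FALSE]))
  if (qrX$rank < ncol(qrX$qr)) {
    piv <- qrX$pivot[seq(qrX$rank + 1L, ncol(qrX$qr))]
    aliased <- colnames(X[, !drop_cols, drop = FALSE])[piv[piv > 1L] - 1L]
    drop_cols[aliased] <- TRUE
  }
  if (any(drop_cols))
    message("inestimable term(s) with degenerate genotype cells dropped: ",
            paste(colnames(X)[drop_cols], collapse = ", "))
  fit <- logistic_fit(X[, !drop_cols, drop = FALSE], st)
  z <- qnorm(0.975)
  est <- fit$coefficients[-1]; se <- fit$se[-1]
  tab <- data.frame(
    term = colnames(X),
    coding = coding,
    or = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
    p_value = NA_real_, estimable = FALSE,
    stringsAsFactors = FALSE
  )
  j <- match(names(est), tab$term)
  tab$or[j] <- exp(est)
  tab$ci_low[j] <- exp(est - z * se)
  tab$ci_high[j] <- exp(est + z * se)
  tab$p_value[j] <- 2 * pnorm(-abs(est / se))
  tab$estimable[j] <- abs(est) <= 15 & is.finite(se)
  rownames(tab) <- NULL
  list(fit = fit, table = tab)
}

#' Backward pruning of a log-additive multivariate model
#'
#' Repeatedly refits the log-additive model, dropping the least significant
#' SNP, until every remaining SNP has p below `alpha`. A pragmatic,
#' non-canonical selection path: the original study does not describe how
#' its multivariate model was reduced, so the procedure is configurable and
#' labelled as this package's own choice.
#'
#' @param gm a `geno_matrix`.
#' @param ph a `phenotype`.
#' @param snps starting SNP set (default all).
#' @param alpha retention threshold (default 0.05).
#' @return list with `snps` (retained ids) and `fit` (final
#'   [multivariate_fit()] result).
#' @export
backward_prune <- function(gm, ph, snps = snp_ids(gm), alpha = 0.05) {
  repeat {
    mv <- multivariate_fit(gm, ph, snps, coding = "log_additive")
    p <- mv$table$p_value
    if (length(snps) == 1L || all(p < alpha, na.rm = TRUE)) break
    worst <- which.max(ifelse(is.na(p), Inf, p))
    snps <- setdiff(snps, mv$table$term[worst])
  }
  list(snps = snps, fit = mv)
}

# ---- power -----------------------------------------------------------------

#' Power of the two-sided allelic test
#'
#' Analytic two-proportion normal-approximation power on allele counts: the
#' case allele frequency is derived from the control frequency and the odds
#' ratio on the odds scale (p1 = OR p0 / (1 - p0 + OR p0)), and
#' power = Phi(|p1 - p0| / SE_alt - z_(1-alpha/2)) with
#' SE_alt = sqrt(p1 q1 / (2 n_case) + p0 q0 / (2 n_control)). A Monte-Carlo
#' mode draws stratum genotypes from the calibrated retrospective model
#' ([expected_genotype_freq_in_stratum()]) and counts rejections of the
#' allelic Wald test.
#'
#' @param n_case,n_control sample sizes.
#' @param control_raf control risk-allele frequency.
#' @param or per-allele odds ratio under the alternative.
#' @param alpha two-sided significance level (default 0.05).
#' @param method `"analytic"` (default) or `"simulation"`.
#' @param n_rep Monte-Carlo replicates (simulation mode).
#' @param prevalence population prevalence assumed by the simulation mode.
#' @param seed seed for the simulation mode.
#' @return analytic mode: the power (scalar). Simulation mode: list with
#'   `power`, `mc_se` and `n_rep`.
#' @examples
#' power_allelic(369, 503, control_raf = 0.59, or = 1.32)  # ~0.80
#' @export
power_allelic <- function(n_case, n_control, control_raf, or, alpha = 0.05,
                          method = c("analytic", "simulation"),
                          n_rep = 2000L, prevalence = 0.005, seed = 1L) {
  method <- match.arg(method)
  stopifnot(control_raf > 0, control_raf < 1, or > 0, alpha > 0, alpha < 1)
  if (method == "analytic") {
    p0 <- control_raf
    p1 <- or * p0 / (1 - p0 + or * p0)
    se_alt <- sqrt(p1 * (1 - p1) / (2 * n_case) +
                   p0 * (1 - p0) / (2 * n_control))
    return(unname(pnorm(abs(p1 - p0) / se_alt - qnorm(1 - alpha / 2))))
  }
  cfg <- cohort_config(variant_panel("snp", control_raf = control_raf),
                       per_allele_or = or, prevalence = prevalence,
                       n_case = n_case, n_control = n_control, seed = seed)
  b0 <- calibrate_intercept(cfg)
  g_case <- expected_genotype_freq_in_stratum(control_raf, or, b0, "case")
  g_ctrl <- expected_genotype_freq_in_stratum(control_raf, or, b0, "control")
  set.seed(seed)
  rej <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    nc <- as.numeric(rmultinom(1, n_case, g_case))
    nk <- as.numeric(rmultinom(1, n_control, g_ctrl))
    a <- nc[2] + 2 * nc[3]; b <- 2 * n_case - a
    c <- nk[2] + 2 * nk[3]; d <- 2 * n_control - c
    res <- allelic_test(two_by_two(a, b, c, d))
    rej[r] <- res$p_value < alpha
  }
  pw <- mean(rej)
  list(power = pw, mc_se = sqrt(pw * (1 - pw) / n_rep), n_rep = n_rep)
}
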