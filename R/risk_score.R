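# Genetic risk scores over a SNP panel (allele-count and weighted), cutoff
# classification metrics, threshold sweeps and ROC/AUC.

#' Allele-count genetic risk score
#'
#' Per-sample sum of risk-oriented dosages over the panel (0 for common-
#' allele homozygotes, 1 heterozygotes, 2 risk homozygotes). Missing
#' genotypes are imputed as twice the pooled risk-allele frequency at that
#' SNP, keeping the sample count fixed; affected samples are flagged.
#'
#' @param gm a `geno_matrix`.
#' @param panel SNP ids to score (default: all SNPs of `gm`).
#' @return data.frame of class `score_profile` (`sample_id`, `score`) with
#'   attributes `score_type` ("count"), `panel`, `weights`, `imputed`
#'   (logical per sample).
#' @export
count_score <- function(gm, panel = NULL) {
  build_score(gm, panel, weights = NULL, score_type = "count")
}

#' Weighted genetic risk score
#'
#' Per-sample sum of per-SNP weight times risk-allele dosage. Default
#' weights are the panel's `weight` column, conventionally the multivariate
#' log-additive odds ratios for the risk-oriented alleles (protective SNPs
#' flipped, weight = reciprocal of the protective OR); any positive weights
#' may be supplied instead (e.g. log-ORs).
#'
#' @param gm a `geno_matrix`.
#' @param panel SNP ids to score (default: all SNPs of `gm`).
#' @param weights positive weights, one per panel SNP (named or positional);
#'   default taken from the variant panel.
#' @return a `score_profile` with `score_type = "weighted"`.
#' @export
weighted_score <- function(gm, panel = NULL, weights = NULL) {
  build_score(gm, panel, weights = weights, score_type = "weighted")
}

build_score <- function(gm, panel, weights, score_type) {
  stopifnot(inherits(gm, "geno_matrix"))
  if (is.null(panel)) panel <- snp_ids(gm)
  if (length(panel) == 0L) stop("empty SNP panel")
  missing_snp <- setdiff(panel, snp_ids(gm))
  if (length(missing_snp))
    stop("panel SNP(s) absent from genotypes: ",
         paste(missing_snp, collapse = ", "))
  if (score_type == "count") {
    w <- rep(1, length(panel))
  } else {
    w <- if (is.null(weights)) {
      gm$variants$weight[match(panel, gm$variants$snp_id)]
    } else if (!is.null(names(weights))) {
      if (!all(panel %in% names(weights)))
        stop("missing weight for: ",
             paste(setdiff(panel, names(weights)), collapse = ", "))
      weights[panel]
    } else {
      if (length(weights) != length(panel))
        stop("need one weight per panel SNP")
      weights
    }
    if (any(is.na(w)) || any(w <= 0)) stop("weights must be positive")
  }
  d <- gm$dosage[, panel, drop = FALSE]
  storage.mode(d) <- "double"
  imputed <- rowSums(is.na(d)) > 0L
  if (any(imputed)) {
    for (j in seq_along(panel)) {
      miss <- is.na(d[, j])
      if (any(miss)) d[miss, j] <- 2 * allele_frequency(gm, panel[j])
    }
  }
  score <- as.numeric(d %*% w)
  structure(data.frame(sample_id = rownames(d), score = score,
                       stringsAsFactors = FALSE),
            score_type = score_type, panel = panel,
            weights = setNames(as.numeric(w), panel), imputed = imputed,
            class = c("score_profile", "data.frame"))
}

#' Classification metrics at one score cutoff
#'
#' For the rule "score >= cutoff predicts disease": sensitivity, specificity,
#' positive/negative predictive value and accuracy (all percentages), plus
#' the 2x2 odds ratio with Wald interval from [allelic_test()].
#'
#' @param n_case_ge,n_control_ge cases / controls at or above the cutoff.
#' @param n_cases,n_controls group totals (must be positive).
#' @param cutoff the cutoff value (carried through).
#' @return one-row data.frame of class `threshold_eval`.
#' @examples
#' classification_metrics(107, 369, 39, 503, cutoff = 7)
#' @export
classification_metrics <- function(n_case_ge, n_cases, n_control_ge,
                                   n_controls, cutoff = NA_real_) {
  if (n_cases <= 0 || n_controls <= 0) stop("group totals must be positive")
  stopifnot(n_case_ge >= 0, n_case_ge <= n_cases,
            n_control_ge >= 0, n_control_ge <= n_controls)
  r <- allelic_test(two_by_two(n_case_ge, n_cases - n_case_ge,
                               n_control_ge, n_controls - n_control_ge),
                    coding = "threshold")
  sens <- 100 * n_case_ge / n_cases
  spec <- 100 * (n_controls - n_control_ge) / n_controls
  ppv <- if (n_case_ge + n_control_ge > 0)
    100 * n_case_ge / (n_case_ge + n_control_ge) else NA_real_
  n_below <- (n_cases - n_case_ge) + (n_controls - n_control_ge)
  npv <- if (n_below > 0)
    100 * (n_controls - n_control_ge) / n_below else NA_real_
  acc <- (sens * n_cases + spec * n_controls) / (n_cases + n_controls)
  structure(data.frame(cutoff = cutoff, n_case_ge = n_case_ge,
                       n_control_ge = n_control_ge, or = r$or,
                       ci_low = r$ci_low, ci_high = r$ci_high,
                       p_value = r$p_value, sensitivity = sens,
                       specificity = spec, ppv = ppv, npv = npv,
                       accuracy = acc, haldane = r$haldane,
                       stringsAsFactors = FALSE),
            class = c("threshold_eval", "data.frame"))
}

#' Evaluate a grid of score cutoffs
#'
#' Applies "score >= cutoff" at each cutoff and computes
#' [classification_metrics()]. The default grid is every distinct observed
#' score (suitable for the integer count score); for continuous weighted
#' scores an explicit grid (e.g. integers) can be supplied.
#'
#' @param case_scores,control_scores numeric score vectors (nonempty).
#' @param cutoffs cutoff grid; default sorted distinct observed scores.
#' @return data.frame, one [classification_metrics()] row per cutoff.
#' @export
threshold_sweep <- function(case_scores, control_scores, cutoffs = NULL) {
  stopifnot(length(case_scores) > 0, length(control_scores) > 0)
  if (is.null(cutoffs))
    cutoffs <- sort(unique(c(case_scores, control_scores)))
  rows <- lapply(cutoffs, function(t) {
    classification_metrics(sum(case_scores >= t), length(case_scores),
                           sum(control_scores >= t), length(control_scores),
                           cutoff = t)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' ROC curve and AUC
#'
#' Points (1 - specificity, sensitivity) over all distinct score cutoffs
#' (plus the trivial endpoints) and the trapezoidal area under them, which
#' equals the Mann-Whitney probability with ties counted one half.
#'
#' @param case_scores,control_scores numeric score vectors (nonempty).
#' @return list of class `roc_curve`: `points` (data.frame `fpr`, `tpr`,
#'   `cutoff`) and `auc`.
#' @export
roc <- function(case_scores, control_scores) {
  stopifnot(length(case_scores) > 0, length(control_scores) > 0)
  if (length(unique(c(case_scores, control_scores))) == 1L)
    warning("constant scores in both groups: AUC is 0.5 by convention")
  cuts <- sort(unique(c(case_scores, control_scores)), decreasing = TRUE)
  tpr <- vapply(cuts, function(t) mean(case_scores >= t), numeric(1))
  fpr <- vapply(cuts, function(t) mean(control_scores >= t), numeric(1))
  pts <- data.frame(fpr = c(0, fpr), tpr = c(0, tpr),
                    cutoff = c(Inf, cuts))
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) +
                              utils::tail(pts$tpr, -1)) / 2)
  structure(list(points = pts, auc = auc), class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> %d points, AUC = %.4f\n", nrow(x$points), x$auc))
  invisible(x)
}

#' Score distribution by bin and group
#'
#' Percentage of cases and of controls in each score bin (left-closed
#' integer bins by default), each group summing to 100.
#'
#' @param profile a `score_profile`.
#' @param ph a `phenotype` covering the profile's samples.
#' @param bins bin lower edges covering the score range; default integers
#'   `floor(min) .. floor(max)`, each bin `[b, b + 1)`.
#' @return data.frame: `bin`, `pct_case`, `pct_control`.
#' @export
score_distribution <- function(profile, ph, bins = NULL) {
  stopifnot(inherits(profile, "score_profile"))
  st <- ph$status[match(profile$sample_id, ph$sample_id)]
  if (anyNA(st)) stop("profile sample(s) absent from phenotype table")
  s <- profile$score
  if (is.null(bins)) bins <- seq(floor(min(s)), floor(max(s)))
  if (min(s) < bins[1]) stop("bins do not cover the score range")
  pct <- function(v) {
    idx <- findInterval(v, bins)
    100 * tabulate(idx, nbins = length(bins)) / length(v)
  }
  data.frame(bin = bins, pct_case = pct(s[st == 1L]),
             pct_control = pct(s[st == 0L]))
}
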