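# Reference tables from the published 22-SNP Ashkenazi Jewish Crohn's disease
# case-control study (369 cases / 503 controls). Values are stored
# risk-oriented: for the two protective IL23R variants the major allele is
# declared the risk allele (is_flipped = TRUE), so their frequencies are
# 1 - printed frequency and their odds ratios the reciprocal of the printed
# (protective) odds ratios.

#' The 22-SNP Crohn's disease reference panel
#'
#' Control and case risk-allele frequencies, univariate allelic odds ratios,
#' and (for the seven SNPs that remained independently significant in the
#' multivariate model) log-additive multivariate odds ratios, all oriented to
#' the risk allele. The `weight` column carries the multivariate OR used by
#' the weighted genetic risk score (1 for non-panel SNPs).
#'
#' @return A `variant_panel` with extra columns `label`, `or_univariate` and
#'   `or_multivariate`.
#' @examples
#' p <- reference_panel()
#' p[p$snp_id %in% significant_panel(), c("snp_id", "gene", "or_multivariate")]
#' @export
reference_panel <- function() {
  tab <- data.frame(
    snp_id = c("rs2066844", "rs2066845", "rs2066847", "rs17221417",
               "rs2076756", "rs11209026", "rs7517847", "rs11805303",
               "rs13361189", "rs11747270", "rs1000113", "rs1373692",
               "rs1992660", "rs4613763", "rs2241880", "rs10210302",
               "rs11190140", "rs6887695", "rs10045431", "rs2542151",
               "rs4263839", "rs744166"),
    gene = c("NOD2", "NOD2", "NOD2", "NOD2", "NOD2", "IL23R", "IL23R",
             "IL23R", "IRGM", "IRGM", "IRGM", "PTGER4", "PTGER4", "PTGER4",
             "ATG16L1", "ATG16L1", "NKX2-3", "IL12B", "IL12B", "PTPN2",
             "TNFSF15", "STAT3"),
    label = c("p.R702W", "p.G908R", "p.L1007fs", "intron 2", "intron 8",
              "R381Q", "intron 6", "intron 6", "intergenic", "intergenic",
              "intergenic", "p.T300A", "near 5'-UTR", "intergenic",
              "intergenic", "intergenic", "near 5'-UTR", "intergenic",
              "intergenic", "intergenic", "intron 1", "intron 1"),
    is_flipped = rep(c(FALSE, TRUE, FALSE), c(5, 2, 15)),
    control_raf = c(0.02, 0.04, 0.02, 0.22, 0.22, 1 - 0.07, 1 - 0.38, 0.35,
                    0.16, 0.15, 0.15, 0.61, 0.60, 0.07, 0.59, 0.59, 0.45,
                    0.32, 0.71, 0.10, 0.76, 0.61),
    case_raf = c(0.04, 0.11, 0.11, 0.38, 0.39, 1 - 0.02, 1 - 0.25, 0.41,
                 0.21, 0.21, 0.21, 0.67, 0.65, 0.08, 0.63, 0.62, 0.43,
                 0.32, 0.69, 0.12, 0.75, 0.62),
    or_univariate = c(1.85, 3.23, 5.18, 2.13, 2.26, 1 / 0.27, 1 / 0.55, 1.32,
                      1.47, 1.48, 1.49, 1.29, 1.21, 1.05, 1.18, 1.14, 0.92,
                      1.03, 0.94, 1.20, 0.95, 0.99),
    or_multivariate = c(2.01, 3.30, 5.24, NA, NA, 1 / 0.43, 1 / 0.59, NA,
                        1.64, NA, NA, 1.37, NA, NA, NA, NA, NA, NA, NA, NA,
                        NA, NA),
    stringsAsFactors = FALSE
  )
  tab$weight <- ifelse(is.na(tab$or_multivariate), 1, tab$or_multivariate)
  out <- as_variant_panel(tab[, c("snp_id", "gene", "is_flipped",
                                  "control_raf", "case_raf", "weight")])
  out$label <- tab$label
  out$or_univariate <- tab$or_univariate
  out$or_multivariate <- tab$or_multivariate
  out
}

#' The seven-SNP significant risk-score panel
#'
#' SNP ids of the variants that remained independently associated in the
#' multivariate model (three NOD2 coding variants, two IL23R variants
#' risk-oriented, one IRGM and one PTGER4 variant); the panel both genetic
#' risk scores are built on.
#'
#' @return character vector of SNP ids.
#' @export
significant_panel <- function() {
  c("rs2066844", "rs2066845", "rs2066847", "rs11209026", "rs7517847",
    "rs13361189", "rs1373692")
}

#' The three NOD2 coding variants
#'
#' @return character vector of SNP ids (p.R702W, p.G908R, p.L1007fs).
#' @export
nod2_coding_panel <- function() c("rs2066844", "rs2066845", "rs2066847")

#' Published per-cutoff classification counts
#'
#' The per-cutoff numbers of cases and controls at or above each score cutoff
#' as printed in the study's threshold table, together with the printed odds
#' ratios. Input for [recompute_threshold_table()], which rebuilds every
#' metric from the counts alone and flags printed odds ratios that the counts
#' do not reproduce.
#'
#' @return data.frame with columns `score_type` ("count"/"weighted"),
#'   `cutoff`, `n_case_ge`, `n_control_ge`, `or_printed`, plus attributes
#'   `n_cases` (369) and `n_controls` (503).
#' @export
reference_threshold_counts <- function() {
  df <- data.frame(
    score_type = rep(c("count", "weighted"), c(6, 10)),
    cutoff = c(3:8, 2:11),
    n_case_ge = c(366, 354, 316, 214, 107, 27,
                  368, 361, 331, 287, 216, 174, 124, 108, 73, 53),
    n_control_ge = c(489, 425, 310, 152, 39, 3,
                     498, 470, 377, 259, 138, 88, 42, 27, 20, 13),
    or_printed = c(3.49, 4.33, 3.71, 3.19, 4.86, 13.16,
                   3.69, 3.17, 2.91, 3.30, 3.73, 4.21, 5.56, 7.69, 9.45,
                   14.2),
    stringsAsFactors = FALSE
  )
  attr(df, "n_cases") <- 369L
  attr(df, "n_controls") <- 503L
  df
}

#' Published classification metrics for the threshold table
#'
#' The full printed rows (sensitivity, specificity, PPV, NPV, accuracy, OR)
#' used by the reproduction tests; see [reference_threshold_counts()] for the
#' counts alone.
#'
#' @return data.frame, one row per printed cutoff.
#' @export
reference_threshold_metrics <- function() {
  counts <- reference_threshold_counts()
  counts$sensitivity <- c(99.2, 95.9, 85.6, 57.9, 29.0, 7.3,
                          99.7, 97.8, 89.7, 77.8, 58.5, 47.2, 33.6, 29.3,
                          19.8, 14.4)
  counts$specificity <- c(2.8, 15.5, 38.4, 69.8, 92.2, 99.4,
                          1.0, 6.6, 25.0, 48.5, 72.6, 82.5, 91.7, 94.6,
                          96.0, 97.4)
  counts$ppv <- c(42.8, 45.4, 50.5, 58.5, 73.3, 90.0,
                  42.5, 43.4, 46.8, 52.6, 61.0, 66.4, 74.7, 80.0, 78.5, 80.3)
  counts$npv <- c(82.4, 83.9, 78.5, 69.4, 63.9, 59.4,
                  83.3, 80.5, 76.8, 74.8, 70.5, 68.0, 65.3, 64.6, 62.0, 60.8)
  counts$accuracy <- c(43.6, 49.5, 58.4, 64.5, 65.5, 60.4,
                       42.8, 45.2, 52.4, 60.9, 66.6, 67.5, 67.1, 67.0, 63.8,
                       62.3)
  counts
}
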