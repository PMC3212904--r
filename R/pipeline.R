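# End-to-end orchestration: simulate or ingest a cohort, run QC, association,
# scores and threshold evaluation, and write a deterministic TSV/JSON report
# bundle.

#' Configure a pipeline run
#'
#' Exactly one of `vcf`/`phenotype` input paths or a simulation block must be
#' given.
#'
#' @param vcf,phenotype,variants input file paths (see [read_genotypes()]).
#' @param simulation a [cohort_config()] to simulate the cohort instead of
#'   reading files.
#' @param panel SNP ids used for the risk scores; default: SNPs whose panel
#'   `weight` differs from 1 if any, otherwise all SNPs.
#' @param weights optional weighted-score weights (see [weighted_score()]).
#' @param cutoffs optional cutoff grid for the threshold sweep.
#' @param alpha nominal significance level annotated in outputs.
#' @param seed seed recorded in the provenance file (the simulation block
#'   carries its own).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(vcf = NULL, phenotype = NULL, variants = NULL,
                            simulation = NULL, panel = NULL, weights = NULL,
                            cutoffs = NULL, alpha = 0.05, seed = 1L) {
  has_files <- !is.null(vcf) || !is.null(phenotype)
  if (has_files == !is.null(simulation))
    stop("give exactly one of {input paths, simulation block}")
  if (has_files && (is.null(vcf) || is.null(phenotype) || is.null(variants)))
    stop("file input needs vcf, phenotype and variants paths")
  if (!(alpha > 0 && alpha < 1)) stop("alpha must lie in (0, 1)")
  structure(list(vcf = vcf, phenotype = phenotype, variants = variants,
                 simulation = simulation, panel = panel, weights = weights,
                 cutoffs = cutoffs, alpha = alpha, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full pipeline
#'
#' Stages: ingest/simulate, HWE and LD QC (controls), univariate allelic
#' scan, multivariate logistic model on the score panel, both risk scores,
#' threshold sweep, ROC and score distributions. Writes `hwe.tsv`, `ld.tsv`,
#' `univariate.tsv`, `multivariate.tsv`, `scores.tsv`, `thresholds.tsv`,
#' `roc.tsv`, `distribution.tsv` and `run.json` (provenance: configuration,
#' seed, package version, timings) into `out_dir`. Identical configuration
#' and seed reproduce every output except the timing fields of `run.json`.
#'
#' @param config a `pipeline_config`.
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the in-memory stage results.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  timings <- list()
  stage <- function(name, expr) {
    message("== stage: ", name)
    st <- Sys.time()
    out <- tryCatch(force(expr), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    timings[[name]] <<- as.numeric(difftime(Sys.time(), st, units = "secs"))
    out
  }
  tsv <- function(df, name) {
    write.table(df, file.path(out_dir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }

  cohort <- stage("input", {
    if (!is.null(config$simulation)) simulate_cohort(config$simulation)
    else read_genotypes(config$vcf, config$phenotype, config$variants)
  })
  gm <- cohort$genotypes; ph <- cohort$phenotypes
  message("   ", nrow(gm$dosage), " samples (",
          sum(ph$status == 1L), " cases / ", sum(ph$status == 0L),
          " controls), ", ncol(gm$dosage), " SNPs")

  panel <- config$panel
  if (is.null(panel)) {
    w <- gm$variants$weight
    panel <- if (any(w != 1)) gm$variants$snp_id[w != 1] else snp_ids(gm)
  }

  hwe <- stage("hwe", hwe_scan(gm, ph, stratum = "control"))
  tsv(hwe, "hwe.tsv")
  ld <- stage("ld", ld_scan(gm, ph, stratum = "control"))
  tsv(ld, "ld.tsv")

  uni <- stage("univariate", univariate_scan(gm, ph))
  uni$significant <- uni$p_value < config$alpha
  tsv(uni, "univariate.tsv")

  mv <- stage("multivariate", {
    rbind(multivariate_fit(gm, ph, panel, "log_additive")$table,
          multivariate_fit(gm, ph, panel, "genotype")$table)
  })
  if (any(!mv$estimable))
    message("   ", sum(!mv$estimable), " inestimable term(s) flagged")
  tsv(mv, "multivariate.tsv")

  scores <- stage("scores", {
    cs <- count_score(gm, panel)
    ws <- weighted_score(gm, panel, config$weights)
    if (any(attr(cs, "imputed")))
      message("   ", sum(attr(cs, "imputed")),
              " sample(s) had missing genotypes mean-imputed")
    data.frame(sample_id = cs$sample_id,
               status = ph$status[match(cs$sample_id, ph$sample_id)],
               count_score = cs$score, weighted_score = ws$score,
               stringsAsFactors = FALSE)
  })
  tsv(scores, "scores.tsv")

  eval_both <- stage("evaluate", {
    out <- lapply(c("count", "weighted"), function(ty) {
      s <- scores[[paste0(ty, "_score")]]
      cuts <- config$cutoffs
      if (is.null(cuts))
        cuts <- if (ty == "count") sort(unique(s))
                else seq(floor(min(s)), ceiling(max(s)))
      sw <- threshold_sweep(s[scores$status == 1L], s[scores$status == 0L],
                            cuts)
      cbind(score_type = ty, sw)
    })
    do.call(rbind, out)
  })
  tsv(eval_both, "thresholds.tsv")

  roc_both <- stage("roc", {
    out <- lapply(c("count", "weighted"), function(ty) {
      s <- scores[[paste0(ty, "_score")]]
      r <- roc(s[scores$status == 1L], s[scores$status == 0L])
      cbind(score_type = ty, r$points, auc = r$auc)
    })
    do.call(rbind, out)
  })
  tsv(roc_both, "roc.tsv")

  dist_both <- stage("distribution", {
    out <- lapply(c("count", "weighted"), function(ty) {
      prof <- if (ty == "count") count_score(gm, panel)
              else weighted_score(gm, panel, config$weights)
      cbind(score_type = ty, score_distribution(prof, ph))
    })
    do.call(rbind, out)
  })
  tsv(dist_both, "distribution.tsv")

  run_info <- list(
    package = "cdgrs",
    version = as.character(packageVersion("cdgrs")),
    seed = config$seed,
    alpha = config$alpha,
    panel = panel,
    n_case = sum(ph$status == 1L),
    n_control = sum(ph$status == 0L),
    n_snps = ncol(gm$dosage),
    simulated = !is.null(config$simulation),
    timings_sec = timings,
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(run_info, file.path(out_dir, "run.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(genotypes = gm, phenotypes = ph, hwe = hwe, ld = ld,
                 univariate = uni, multivariate = mv, scores = scores,
                 thresholds = eval_both, roc = roc_both,
                 distribution = dist_both, run_info = run_info))
}

#' Recompute a published threshold table from its counts
#'
#' Rebuilds every classification metric from per-cutoff case/control counts
#' alone via [classification_metrics()], and, when a printed odds ratio is
#' supplied, flags rows whose printed OR differs from the recomputed one by
#' more than `tol` (relative) — exposing rows whose published OR cannot be
#' the cross-product of the published counts.
#'
#' @param counts data.frame with columns `cutoff`, `n_case_ge`,
#'   `n_control_ge`, optionally `score_type` and `or_printed`; a path to such
#'   a TSV is also accepted. Defaults to the packaged
#'   [reference_threshold_counts()].
#' @param n_cases,n_controls group totals; default from the `counts`
#'   attributes, else the reference 369/503.
#' @param tol relative OR discrepancy that triggers the flag (default 0.01).
#' @return data.frame of recomputed rows with columns `or_printed` and
#'   `or_consistent` appended when printed ORs were given.
#' @export
recompute_threshold_table <- function(counts = reference_threshold_counts(),
                                      n_cases = NULL, n_controls = NULL,
                                      tol = 0.01) {
  if (is.character(counts)) counts <- read.delim(counts)
  need <- c("cutoff", "n_case_ge", "n_control_ge")
  if (!all(need %in% names(counts)))
    stop("counts must have columns: ", paste(need, collapse = ", "))
  if (is.null(n_cases)) n_cases <- attr(counts, "n_cases")
  if (is.null(n_controls)) n_controls <- attr(counts, "n_controls")
  if (is.null(n_cases) || is.null(n_controls))
    stop("group totals must be supplied (n_cases, n_controls)")
  rows <- lapply(seq_len(nrow(counts)), function(i) {
    classification_metrics(counts$n_case_ge[i], n_cases,
                           counts$n_control_ge[i], n_controls,
                           cutoff = counts$cutoff[i])
  })
  out <- do.call(rbind, rows)
  if ("score_type" %in% names(counts))
    out <- cbind(score_type = counts$score_type, out)
  if ("or_printed" %in% names(counts)) {
    out$or_printed <- counts$or_printed
    out$or_consistent <- abs(out$or / out$or_printed - 1) <= tol
  }
  rownames(out) <- NULL
  out
}
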