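# Domain containers: variant panels, genotype dosage matrices, phenotypes,
# 2x2 tables. Dosage counts copies of the risk-oriented allele (0/1/2);
# protective variants are stored flipped so every panel allele points in the
# risk direction.

#' Construct a variant panel
#'
#' A variant panel describes the SNPs of a study: identity, gene label, the
#' risk-oriented allele, whether that allele is the major/reference allele of
#' a protective variant (`is_flipped`), the control risk-allele frequency and
#' an optional per-allele score weight.
#'
#' @param snp_id character vector of unique SNP identifiers (e.g. "rs2066847").
#' @param gene gene or locus labels (recycled if length 1).
#' @param risk_allele risk-oriented allele as a nucleotide or allele tag; `NA`
#'   allowed when genotypes are supplied as dosages rather than VCF calls.
#' @param is_flipped logical; `TRUE` when the risk-oriented allele is the
#'   major/reference allele (protective variants represented risk-oriented).
#' @param control_raf risk-allele frequency among controls, in \[0, 1\].
#' @param case_raf optional risk-allele frequency among cases.
#' @param weight positive per-allele risk-score weight (default 1).
#' @return A `data.frame` with class `variant_panel`, one row per SNP.
#' @examples
#' variant_panel("rs2066847", gene = "NOD2", control_raf = 0.02, weight = 5.24)
#' @export
variant_panel <- function(snp_id, gene = NA_character_, risk_allele = NA_character_,
                          is_flipped = FALSE, control_raf = NA_real_,
                          case_raf = NA_real_, weight = 1) {
  snp_id <- as.character(snp_id)
  if (anyDuplicated(snp_id))
    stop("duplicated snp_id in variant panel: ",
         paste(unique(snp_id[duplicated(snp_id)]), collapse = ", "))
  n <- length(snp_id)
  panel <- data.frame(
    snp_id      = snp_id,
    gene        = rep_len(as.character(gene), n),
    risk_allele = rep_len(as.character(risk_allele), n),
    is_flipped  = rep_len(as.logical(is_flipped), n),
    control_raf = rep_len(as.numeric(control_raf), n),
    case_raf    = rep_len(as.numeric(case_raf), n),
    weight      = rep_len(as.numeric(weight), n),
    stringsAsFactors = FALSE
  )
  bad <- !is.na(panel$control_raf) & (panel$control_raf < 0 | panel$control_raf > 1)
  if (any(bad)) stop("control_raf outside [0, 1] for: ",
                     paste(panel$snp_id[bad], collapse = ", "))
  if (any(!is.na(panel$weight) & panel$weight <= 0))
    stop("weights must be positive")
  class(panel) <- c("variant_panel", "data.frame")
  panel
}

#' Coerce a data frame to a variant panel
#'
#' Missing columns are filled with their defaults (`is_flipped = FALSE`,
#' `weight = 1`).
#'
#' @param x data.frame with at least a `snp_id` column.
#' @return A `variant_panel`.
#' @export
as_variant_panel <- function(x) {
  if (inherits(x, "variant_panel")) return(x)
  stopifnot(is.data.frame(x), "snp_id" %in% names(x))
  get0_ <- function(col, default) if (col %in% names(x)) x[[col]] else default
  variant_panel(
    snp_id      = x$snp_id,
    gene        = get0_("gene", NA_character_),
    risk_allele = get0_("risk_allele", NA_character_),
    is_flipped  = get0_("is_flipped", FALSE),
    control_raf = get0_("control_raf", NA_real_),
    case_raf    = get0_("case_raf", NA_real_),
    weight      = get0_("weight", 1)
  )
}

#' Construct a genotype matrix
#'
#' Samples-by-variants risk-allele dosage table. Dosages count copies of the
#' risk-oriented allele: 0 for common-allele homozygotes, 1 for heterozygotes,
#' 2 for risk-allele homozygotes; `NA` marks a missing genotype call.
#'
#' @param dosage integer matrix (samples x variants) with values in
#'   \{0, 1, 2, NA\}; rownames are sample ids, colnames SNP ids.
#' @param variants optional `variant_panel` matching the columns; a minimal
#'   panel is derived from column names when omitted.
#' @return An object of class `geno_matrix` with elements `dosage` and
#'   `variants`.
#' @export
genotype_matrix <- function(dosage, variants = NULL) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  if (is.null(colnames(dosage))) stop("dosage matrix needs SNP column names")
  if (is.null(rownames(dosage)))
    rownames(dosage) <- sprintf("S%05d", seq_len(nrow(dosage)))
  vals <- dosage[!is.na(dosage)]
  if (length(vals) && (min(vals) < 0L || max(vals) > 2L))
    stop("dosages must lie in {0, 1, 2} or be NA")
  if (is.null(variants)) {
    variants <- variant_panel(colnames(dosage))
  } else {
    variants <- as_variant_panel(variants)
    if (!identical(variants$snp_id, colnames(dosage)))
      stop("variant panel snp_ids must match dosage column names in order")
  }
  structure(list(dosage = dosage, variants = variants), class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("<geno_matrix> %d samples x %d variants\n",
              nrow(x$dosage), ncol(x$dosage)))
  cat("  SNPs:", paste(utils::head(colnames(x$dosage), 6), collapse = ", "),
      if (ncol(x$dosage) > 6) "..." else "", "\n")
  miss <- mean(is.na(x$dosage))
  if (miss > 0) cat(sprintf("  missing calls: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$dosage)

sample_ids <- function(gm) rownames(gm$dosage)
snp_ids    <- function(gm) colnames(gm$dosage)

#' Construct a phenotype vector
#'
#' @param sample_id character vector of unique sample ids.
#' @param status case/control status: 1/0, logical, or "case"/"control".
#' @return `data.frame` of class `phenotype` with columns `sample_id` and
#'   `status` (integer, 1 = case, 0 = control).
#' @export
phenotype_vector <- function(sample_id, status) {
  sample_id <- as.character(sample_id)
  if (anyDuplicated(sample_id))
    stop("duplicated sample ids in phenotype table")
  if (is.character(status) || is.factor(status)) {
    status <- match.arg(as.character(status), c("control", "case"),
                        several.ok = TRUE)
    status <- as.integer(status == "case")
  }
  status <- as.integer(status)
  if (length(status) != length(sample_id) || any(!status %in% c(0L, 1L)))
    stop("status must be one value in {0 = control, 1 = case} per sample")
  structure(data.frame(sample_id = sample_id, status = status,
                       stringsAsFactors = FALSE),
            class = c("phenotype", "data.frame"))
}

#' A 2x2 exposure-by-status table
#'
#' The atom of every odds-ratio computation: `a` exposed cases, `b` unexposed
#' cases, `c` exposed controls, `d` unexposed controls.
#'
#' @param a,b,c,d nonnegative counts.
#' @return list of class `two_by_two`.
#' @export
two_by_two <- function(a, b, c, d) {
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(counts < 0) || any(is.na(counts))) stop("counts must be nonnegative")
  structure(as.list(counts), class = "two_by_two")
}

# ---- readers / writers -----------------------------------------------------

#' Read genotypes from VCF with a phenotype table and variant panel
#'
#' Extracts diploid GT calls at the panel SNPs and converts them to
#' risk-oriented dosages: the ALT-allele count when the risk allele is ALT,
#' and `2 - count` when the risk allele is REF (protective variants). Missing
#' calls (`./.`) become `NA`. VCF samples absent from the phenotype table are
#' dropped with a warning; phenotype samples absent from the VCF are an error.
#'
#' @param vcf_file path to a VCF 4.x file (only the GT field is consulted).
#' @param phenotype path to a TSV with columns `sample_id`, `status`
#'   (1 = case, 0 = control), or a `phenotype` object.
#' @param variants a `variant_panel` (or coercible data.frame / path to a TSV
#'   with columns snp_id, gene, risk_allele, is_flipped, weight).
#' @return list with elements `genotypes` (`geno_matrix`) and `phenotypes`
#'   (`phenotype`).
#' @export
read_genotypes <- function(vcf_file, phenotype, variants) {
  if (is.character(variants)) variants <- read_variant_panel(variants)
  variants <- as_variant_panel(variants)
  if (is.character(phenotype)) phenotype <- read_phenotype_tsv(phenotype)
  stopifnot(inherits(phenotype, "phenotype"))

  vcf <- vcfR::read.vcfR(vcf_file, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  ids <- fix[, "ID"]
  hit <- match(variants$snp_id, ids)
  if (anyNA(hit))
    stop("variant(s) absent from VCF: ",
         paste(variants$snp_id[is.na(hit)], collapse = ", "))
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1,
                                     dimnames = list(ids[1], names(gt)))
  gt <- gt[hit, , drop = FALSE]
  fix <- fix[hit, , drop = FALSE]

  multi <- grepl(",", fix[, "ALT"])
  if (any(multi))
    stop("multiallelic site(s) not supported: ",
         paste(variants$snp_id[multi], collapse = ", "))

  vcf_samples <- colnames(gt)
  missing_ph <- setdiff(phenotype$sample_id, vcf_samples)
  if (length(missing_ph))
    stop("phenotype sample(s) absent from VCF: ",
         paste(missing_ph, collapse = ", "))
  extra <- setdiff(vcf_samples, phenotype$sample_id)
  if (length(extra))
    warning(length(extra), " VCF sample(s) absent from phenotype table dropped: ",
            paste(utils::head(extra, 5), collapse = ", "),
            if (length(extra) > 5) " ..." else "")
  keep <- phenotype$sample_id
  gt <- gt[, keep, drop = FALSE]

  dos <- matrix(NA_integer_, nrow = length(keep), ncol = nrow(variants),
                dimnames = list(keep, variants$snp_id))
  for (j in seq_len(nrow(variants))) {
    alt_count <- parse_gt_alt_count(gt[j, ], variants$snp_id[j])
    ra <- variants$risk_allele[j]
    if (!is.na(ra) && ra == fix[j, "REF"]) {
      alt_count <- 2L - alt_count
    } else if (!is.na(ra) && ra != fix[j, "ALT"]) {
      stop("risk allele of ", variants$snp_id[j],
           " matches neither REF nor ALT in VCF")
    } else if (is.na(ra) && isTRUE(variants$is_flipped[j])) {
      alt_count <- 2L - alt_count
    }
    dos[, j] <- alt_count
  }
  list(genotypes = genotype_matrix(dos, variants), phenotypes = phenotype)
}

# diploid GT string -> ALT allele count (NA for missing), hard error otherwise
parse_gt_alt_count <- function(gt, snp) {
  out <- rep(NA_integer_, length(gt))
  ok <- !is.na(gt)
  parts <- strsplit(gt[ok], "[/|]")
  nall <- lengths(parts)
  if (any(nall != 2L))
    stop("non-diploid GT at ", snp, ": ", gt[ok][which(nall != 2L)[1]])
  al <- unlist(parts)
  if (!all(al %in% c("0", "1", ".")))
    stop("unsupported allele code in GT at ", snp)
  cnt <- vapply(parts, function(p) {
    if (any(p == ".")) NA_integer_ else sum(p == "1")
  }, integer(1))
  out[ok] <- cnt
  out
}

#' Read / write the internal genotype TSV dialect
#'
#' A human-checkable exchange format: first column `sample_id`, one column per
#' SNP (header = snp_id), cells in \{0, 1, 2, NA\}.
#'
#' @param gm a `geno_matrix`.
#' @param path file path.
#' @param variants optional `variant_panel` to attach on read.
#' @return `write_genotype_tsv` returns `path` invisibly;
#'   `read_genotype_tsv` returns a `geno_matrix`.
#' @export
write_genotype_tsv <- function(gm, path) {
  df <- data.frame(sample_id = sample_ids(gm), gm$dosage,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_genotype_tsv
#' @export
read_genotype_tsv <- function(path, variants = NULL) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  stopifnot(names(df)[1] == "sample_id")
  dos <- as.matrix(df[, -1, drop = FALSE])
  rownames(dos) <- df$sample_id
  genotype_matrix(dos, variants)
}

#' Read / write phenotype TSV (sample_id, status with 1 = case, 0 = control)
#'
#' @param ph a `phenotype`.
#' @param path file path.
#' @return `read_phenotype_tsv` returns a `phenotype`.
#' @export
write_phenotype_tsv <- function(ph, path) {
  write.table(as.data.frame(ph), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_phenotype_tsv
#' @export
read_phenotype_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  phenotype_vector(df$sample_id, df$status)
}

#' Read a variant panel from TSV or JSON
#'
#' @param path file ending in `.json` for JSON, otherwise parsed as TSV.
#' @return A `variant_panel`.
#' @export
read_variant_panel <- function(path) {
  df <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    as.data.frame(jsonlite::fromJSON(path))
  } else {
    read.delim(path, stringsAsFactors = FALSE)
  }
  as_variant_panel(df)
}

#' Write a genotype matrix as a minimal VCF (synthetic contig, GT only)
#'
#' Positions are dummies (1, 2, ...); REF/ALT come from the panel's
#' `risk_allele` orientation ("A"/"B" tags when alleles are unnamed). Used to
#' round-trip simulated cohorts through the VCF reader.
#'
#' @param gm a `geno_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  v <- gm$variants
  ref <- ifelse(is.na(v$risk_allele), "A",
                ifelse(v$is_flipped, v$risk_allele, "A"))
  alt <- ifelse(is.na(v$risk_allele), "B",
                ifelse(v$is_flipped, "B", v$risk_allele))
  # dosage counts risk alleles; VCF GT counts ALT alleles
  alt_dos <- gm$dosage
  flip <- which(v$is_flipped)
  if (length(flip)) alt_dos[, flip] <- 2L - alt_dos[, flip]
  gt_code <- c("0/0", "0/1", "1/1")
  lines <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chrSim>",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_ids(gm)), collapse = "\t")
  )
  body <- vapply(seq_len(ncol(alt_dos)), function(j) {
    gts <- ifelse(is.na(alt_dos[, j]), "./.", gt_code[alt_dos[, j] + 1L])
    paste(c("chrSim", j, v$snp_id[j], ref[j], alt[j], ".", "PASS", ".",
            "GT", gts), collapse = "\t")
  }, character(1))
  writeLines(c(lines, body), path)
  invisible(path)
}

# ---- basic operations ------------------------------------------------------

#' Split a genotype matrix by case/control status
#'
#' @param gm a `geno_matrix`.
#' @param ph a `phenotype` covering every sample of `gm`.
#' @return list with `geno_matrix` elements `case` and `control`, each
#'   preserving the input sample order.
#' @export
split_by_status <- function(gm, ph) {
  stopifnot(inherits(gm, "geno_matrix"), inherits(ph, "phenotype"))
  idx <- match(sample_ids(gm), ph$sample_id)
  if (anyNA(idx))
    stop("sample(s) in genotype matrix absent from phenotype table: ",
         paste(sample_ids(gm)[is.na(idx)][1:min(5, sum(is.na(idx)))],
               collapse = ", "))
  st <- ph$status[idx]
  sub <- function(keep) genotype_matrix(gm$dosage[keep, , drop = FALSE],
                                        gm$variants)
  list(case = sub(st == 1L), control = sub(st == 0L))
}

#' Risk-allele frequency at one SNP
#'
#' Sum of dosages over twice the number of non-missing genotypes.
#'
#' @param gm a `geno_matrix`.
#' @param snp_id SNP identifier.
#' @return frequency in \[0, 1\].
#' @export
allele_frequency <- function(gm, snp_id) {
  if (!snp_id %in% snp_ids(gm)) stop("unknown SNP: ", snp_id)
  d <- gm$dosage[, snp_id]
  n <- sum(!is.na(d))
  if (n == 0L) stop("all genotypes missing at ", snp_id)
  sum(d, na.rm = TRUE) / (2 * n)
}

#' Flip the risk-allele orientation of one SNP
#'
#' Replaces dosages by `2 - dosage` and toggles `is_flipped`; applying the
#' flip twice restores the original matrix.
#'
#' @param gm a `geno_matrix`.
#' @param snp_id SNP identifier to flip.
#' @return the modified `geno_matrix`.
#' @export
flip_variant <- function(gm, snp_id) {
  if (!snp_id %in% snp_ids(gm)) stop("unknown SNP: ", snp_id)
  gm$dosage[, snp_id] <- 2L - gm$dosage[, snp_id]
  j <- match(snp_id, gm$variants$snp_id)
  gm$variants$is_flipped[j] <- !gm$variants$is_flipped[j]
  if (!is.na(gm$variants$control_raf[j]))
    gm$variants$control_raf[j] <- 1 - gm$variants$control_raf[j]
  if (!is.na(gm$variants$case_raf[j]))
    gm$variants$case_raf[j] <- 1 - gm$variants$case_raf[j]
  gm
}
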