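test_that("VCF genotypes become risk-oriented dosages", {
  vcf <- write_test_vcf()
  ph <- phenotype_vector(c("s1", "s2", "s3"), c(1, 0, 0))
  expect_warning(read_genotypes(vcf, ph, test_vcf_panel()),
                 "absent from phenotype")
  res <- suppressWarnings(read_genotypes(vcf, ph, test_vcf_panel()))
  d <- res$genotypes$dosage
  # rs1: risk = ALT, direct ALT count
  expect_identical(unname(d[, "rs1"]), c(2L, 1L, 0L))
  # rs2: risk = REF, count flipped (0/1 -> 1, 0/0 -> 2, ./. -> NA)
  expect_identical(unname(d[, "rs2"]), c(1L, 2L, NA))
  expect_identical(rownames(d), c("s1", "s2", "s3"))
})

test_that("VCF reader rejects bad input", {
  vcf <- write_test_vcf()
  ph <- phenotype_vector(c("s1", "s2", "s3", "s4"), c(1, 0, 0, 1))
  bad_panel <- variant_panel("rs999", risk_allele = "A")
  expect_error(read_genotypes(vcf, ph, bad_panel), "rs999")
  # phenotype sample missing from VCF
  ph2 <- phenotype_vector(c("s1", "ghost"), c(1, 0))
  expect_error(read_genotypes(vcf, ph2, test_vcf_panel()), "ghost")
  # risk allele matching neither REF nor ALT
  wrong <- variant_panel(c("rs1", "rs2"), risk_allele = c("T", "C"),
                         is_flipped = c(FALSE, TRUE))
  expect_error(read_genotypes(vcf, ph, wrong), "neither REF nor ALT")
})

test_that("multiallelic and non-diploid records are hard errors", {
  path <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1>",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "s1"), collapse = "\t"),
    paste(c("chr1", "1", "rsM", "A", "G,T", ".", "PASS", ".", "GT", "0/1"),
          collapse = "\t")
  ), path)
  ph <- phenotype_vector("s1", 1)
  expect_error(
    read_genotypes(path, ph, variant_panel("rsM", risk_allele = "G")),
    "multiallelic")

  path2 <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1>",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "s1"), collapse = "\t"),
    paste(c("chr1", "1", "rsH", "A", "G", ".", "PASS", ".", "GT", "1"),
          collapse = "\t")
  ), path2)
  expect_error(
    read_genotypes(path2, ph, variant_panel("rsH", risk_allele = "G")),
    "non-diploid")
})

test_that("genotype TSV round-trips dosage and missingness exactly", {
  gm <- make_gm(rsX = c(0L, 1L, 2L, NA), rsY = c(2L, NA, 0L, 1L))
  path <- tempfile(fileext = ".tsv")
  write_genotype_tsv(gm, path)
  back <- read_genotype_tsv(path)
  expect_identical(back$dosage, gm$dosage)
})

test_that("risk-allele flip is an involution", {
  gm <- make_gm(rsX = c(0L, 1L, 2L, NA))
  gm$variants$control_raf <- 0.2
  once <- flip_variant(gm, "rsX")
  expect_identical(unname(once$dosage[, 1]), c(2L, 1L, 0L, NA))
  expect_true(once$variants$is_flipped)
  expect_equal(once$variants$control_raf, 0.8)
  twice <- flip_variant(once, "rsX")
  expect_identical(twice$dosage, gm$dosage)
  expect_identical(twice$variants$is_flipped, FALSE)
  expect_equal(twice$variants$control_raf, 0.2)
})

test_that("allele_frequency counts risk alleles over non-missing calls", {
  expect_equal(allele_frequency(make_gm(s = c(0L, 1L, 2L)), "s"), 0.5)
  expect_equal(allele_frequency(make_gm(s = rep(0L, 4)), "s"), 0)
  expect_equal(allele_frequency(make_gm(s = c(2L, 2L)), "s"), 1)
  expect_equal(allele_frequency(make_gm(s = c(0L, 1L, 2L, NA)), "s"), 0.5)
  expect_error(allele_frequency(make_gm(s = c(NA, NA)), "s"), "missing")
  expect_error(allele_frequency(make_gm(s = 0L), "nope"), "unknown")
})

test_that("case/control frequencies recompose the pooled frequency", {
  set.seed(41)
  for (rep in 1:20) {
    d <- sample(c(0:2, NA), 30, replace = TRUE, prob = c(.4, .3, .2, .1))
    if (all(is.na(d))) next
    gm <- make_gm(s = d)
    st <- sample(0:1, 30, replace = TRUE)
    if (!any(st == 1) || !any(st == 0)) next
    ph <- phenotype_vector(rownames(gm$dosage), st)
    sp <- split_by_status(gm, ph)
    n_ca <- sum(!is.na(sp$case$dosage)); n_co <- sum(!is.na(sp$control$dosage))
    f_ca <- if (n_ca) allele_frequency(sp$case, "s") else 0
    f_co <- if (n_co) allele_frequency(sp$control, "s") else 0
    expect_equal((f_ca * n_ca + f_co * n_co) / (n_ca + n_co),
                 allele_frequency(gm, "s"))
  }
})

test_that("split_by_status partitions and preserves order", {
  gm <- make_gm(s = c(0L, 1L, 2L, 1L, 0L, 2L, 1L, 0L))
  ph <- phenotype_vector(paste0("s", 1:8), c(1, 1, 0, 1, 0, 1, 1, 0))
  sp <- split_by_status(gm, ph)
  expect_equal(nrow(sp$case$dosage), 5)
  expect_equal(nrow(sp$control$dosage), 3)
  expect_identical(rownames(sp$case$dosage), paste0("s", c(1, 2, 4, 6, 7)))

  all_case <- phenotype_vector(paste0("s", 1:8), rep(1, 8))
  sp2 <- split_by_status(gm, all_case)
  expect_equal(nrow(sp2$control$dosage), 0)

  disjoint <- phenotype_vector(paste0("x", 1:8), rep(1, 8))
  expect_error(split_by_status(gm, disjoint), "absent from phenotype")
})

test_that("VCF writer round-trips a simulated cohort", {
  sim <- simulate_cohort(cohort_config(
    variant_panel(c("v1", "v2"), risk_allele = c("G", "T"),
                  control_raf = c(0.3, 0.6)),
    per_allele_or = c(1.5, 1), prevalence = 0.3,
    n_case = 30, n_control = 40, seed = 9))
  path <- tempfile(fileext = ".vcf")
  write_vcf(sim$genotypes, path)
  back <- read_genotypes(path, sim$phenotypes, sim$genotypes$variants)
  expect_identical(back$genotypes$dosage, sim$genotypes$dosage)
})
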