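# Shared fixture builders (everything generated in code).

# genotype matrix from per-SNP dosage vectors
make_gm <- function(..., variants = NULL, samples = NULL) {
  cols <- list(...)
  d <- do.call(cbind, cols)
  colnames(d) <- names(cols)
  rownames(d) <- if (is.null(samples)) paste0("s", seq_len(nrow(d))) else samples
  genotype_matrix(d, variants)
}

# tiny VCF: rs1 risk allele = ALT (G), rs2 risk allele = REF (C, flipped),
# samples s1..s4; s3 has a missing call at rs2
write_test_vcf <- function(path = tempfile(fileext = ".vcf")) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1>",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "s1", "s2", "s3", "s4"), collapse = "\t"),
    paste(c("chr1", "100", "rs1", "A", "G", ".", "PASS", ".", "GT",
            "1/1", "0/1", "0/0", "0/1"), collapse = "\t"),
    paste(c("chr1", "200", "rs2", "C", "T", ".", "PASS", ".", "GT",
            "0/1", "0/0", "./.", "1/1"), collapse = "\t")
  ), path)
  path
}

test_vcf_panel <- function() {
  variant_panel(c("rs1", "rs2"), risk_allele = c("G", "C"),
                is_flipped = c(FALSE, TRUE))
}

# random two_by_two with all-positive cells
random_table <- function() {
  two_by_two(sample(1:80, 1), sample(1:80, 1), sample(1:80, 1),
             sample(1:80, 1))
}

# observed-data log-likelihood of a 3x3 genotype table at haplotype
# frequencies (pAB, pA - pAB, pB - pAB, 1 - pA - pB + pAB); independent
# grid-search oracle for ld_em
geno_table_loglik <- function(n, pA, pB, pAB) {
  h <- c(pAB, pA - pAB, pB - pAB, 1 - pA - pB + pAB)
  if (any(h < 0)) return(-Inf)
  hd <- c(1, 1, 0, 0); hb <- c(1, 0, 1, 0)
  P <- matrix(0, 3, 3)
  for (x in 1:4) for (y in 1:4) {
    i <- hd[x] + hd[y]; j <- hb[x] + hb[y]
    P[i + 1, j + 1] <- P[i + 1, j + 1] + h[x] * h[y]
  }
  sum(n[n > 0] * log(P[n > 0]))
}

# dosage vectors realizing a 3x3 genotype cross-table (rows = SNP a dosage)
table_to_dosages <- function(n) {
  da <- rep(rep(0:2, each = 3), as.vector(t(n)))
  db <- rep(rep(0:2, times = 3), as.vector(t(n)))
  list(a = da, b = db)
}
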