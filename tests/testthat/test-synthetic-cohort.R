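test_that("intercept calibration matches closed forms under no genetic effect", {
  base <- variant_panel(c("a", "b"), control_raf = c(0.3, 0.6))
  cfg <- cohort_config(base, per_allele_or = 1, prevalence = 0.2,
                       n_case = 10, n_control = 10)
  expect_equal(calibrate_intercept(cfg), log(0.2 / 0.8), tolerance = 1e-6)
  cfg5 <- cohort_config(base, per_allele_or = 1, prevalence = 0.5,
                        n_case = 10, n_control = 10)
  expect_equal(calibrate_intercept(cfg5), 0, tolerance = 1e-6)
})

test_that("intercept calibration matches a brute-force single-SNP oracle", {
  cfg <- cohort_config(variant_panel("x", control_raf = 0.5),
                       per_allele_or = 2, prevalence = 0.1,
                       n_case = 10, n_control = 10)
  # independent oracle: solve the 3-genotype expectation directly
  g <- c(0.25, 0.5, 0.25)
  f <- function(b) sum(g * plogis(b + log(2) * (0:2))) - 0.1
  oracle <- uniroot(f, c(-30, 10), tol = 1e-12)$root
  expect_equal(calibrate_intercept(cfg), oracle, tolerance = 1e-5)
})

test_that("haplotype pair construction honours D' targets", {
  le <- make_haplotype_pair(0.3, 0.7, 0)
  expect_equal(le[["freq_AB"]], 0.3 * 0.7)
  lim <- make_haplotype_pair(0.5, 0.5, 1)
  expect_equal(unclass(lim),
               c(freq_AB = 0.5, freq_Ab = 0, freq_aB = 0, freq_ab = 0.5))
  expect_error(make_haplotype_pair(0.5, 0.5, 1.2))
  # marginals reproduce the input frequencies for random draws
  set.seed(5)
  for (i in 1:25) {
    pa <- runif(1, 0.05, 0.95); pb <- runif(1, 0.05, 0.95)
    d <- runif(1, -1, 1)
    h <- make_haplotype_pair(pa, pb, d)
    expect_equal(sum(h), 1, tolerance = 1e-12)
    expect_equal(h[["freq_AB"]] + h[["freq_Ab"]], pa, tolerance = 1e-9)
    expect_equal(h[["freq_AB"]] + h[["freq_aB"]], pb, tolerance = 1e-9)
  }
})

test_that("same seed gives byte-identical cohorts", {
  cfg <- cohort_config(variant_panel(c("a", "b"), control_raf = c(0.2, 0.5)),
                       per_allele_or = c(2, 1), prevalence = 0.2,
                       n_case = 40, n_control = 60, seed = 123)
  s1 <- simulate_cohort(cfg); s2 <- simulate_cohort(cfg)
  expect_identical(s1$genotypes$dosage, s2$genotypes$dosage)
  expect_identical(s1$phenotypes$status, s2$phenotypes$status)
  p1 <- tempfile(); p2 <- tempfile()
  write_genotype_tsv(s1$genotypes, p1); write_genotype_tsv(s2$genotypes, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("null model: case and control frequencies agree within noise", {
  for (s in 1:10) {
    cfg <- cohort_config(variant_panel("x", control_raf = 0.3),
                         per_allele_or = 1, prevalence = 0.2,
                         n_case = 150, n_control = 150, seed = s)
    sim <- simulate_cohort(cfg)
    sp <- split_by_status(sim$genotypes, sim$phenotypes)
    diff <- allele_frequency(sp$case, "x") - allele_frequency(sp$control, "x")
    se <- sqrt(0.3 * 0.7 / (2 * 150) + 0.3 * 0.7 / (2 * 150))
    expect_lt(abs(diff), 3 * se)
  }
})

test_that("realized prevalence before truncation tracks the target", {
  cfg <- cohort_config(variant_panel("x", control_raf = 0.2),
                       per_allele_or = 3, prevalence = 0.1,
                       n_case = 200, n_control = 200, seed = 77)
  sim <- simulate_cohort(cfg)
  info <- sim$sim_info
  se <- sqrt(0.1 * 0.9 / info$total_drawn)
  expect_lt(abs(info$realized_prevalence - 0.1), 3 * se)
})

test_that("sampling cap triggers a diagnostic error", {
  cfg <- cohort_config(variant_panel("x", control_raf = 0.2),
                       per_allele_or = 1, prevalence = 0.001,
                       n_case = 500, n_control = 10, seed = 1,
                       max_draw_factor = 0.01)
  expect_error(simulate_cohort(cfg), "cap")
})

test_that("stratum genotype frequencies: analytic Bayes inversion", {
  # independence when the SNP has no effect
  expect_equal(expected_genotype_freq_in_stratum(0.3, 1, -2, "case"),
               c(0.49, 0.42, 0.09))
  # normalization over random parameters
  set.seed(8)
  for (i in 1:20) {
    v <- expected_genotype_freq_in_stratum(runif(1, .05, .95),
                                           exp(runif(1, -1.5, 1.5)),
                                           runif(1, -6, 0),
                                           sample(c("case", "control"), 1))
    expect_equal(sum(v), 1, tolerance = 1e-12)
    expect_true(all(v >= 0))
  }
})

test_that("simulated stratum frequencies match the analytic oracle", {
  cfg <- cohort_config(variant_panel("x", control_raf = 0.2),
                       per_allele_or = 3, prevalence = 0.05,
                       n_case = 2000, n_control = 2000, seed = 31)
  sim <- simulate_cohort(cfg)
  sp <- split_by_status(sim$genotypes, sim$phenotypes)
  b0 <- sim$sim_info$intercept
  for (stratum in c("case", "control")) {
    expected <- expected_genotype_freq_in_stratum(0.2, 3, b0, stratum)
    d <- sp[[stratum]]$dosage[, "x"]
    obs <- tabulate(d + 1L, 3) / length(d)
    se <- sqrt(expected * (1 - expected) / length(d))
    expect_true(all(abs(obs - expected) < 3 * pmax(se, 1e-3)))
  }
})

test_that("target D' survives a round trip through simulation and EM", {
  pairs <- data.frame(snp_a = "a", snp_b = "b", d_prime = 0.8)
  cfg <- cohort_config(variant_panel(c("a", "b"), control_raf = c(0.3, 0.4)),
                       per_allele_or = 1, prevalence = 0.5,
                       n_case = 1500, n_control = 1500, ld_pairs = pairs,
                       seed = 13)
  sim <- simulate_cohort(cfg)
  ld <- ld_scan(sim$genotypes, sim$phenotypes, stratum = "pooled")
  expect_equal(ld$d_prime, 0.8, tolerance = 0.05)

  # strong LD between a common and a rare SNP
  pairs2 <- data.frame(snp_a = "a", snp_b = "b", d_prime = 0.99)
  cfg2 <- cohort_config(variant_panel(c("a", "b"), control_raf = c(0.22, 0.04)),
                        per_allele_or = 1, prevalence = 0.5,
                        n_case = 4000, n_control = 4000, ld_pairs = pairs2,
                        seed = 17)
  sim2 <- simulate_cohort(cfg2)
  ld2 <- ld_scan(sim2$genotypes, sim2$phenotypes, stratum = "pooled")
  expect_equal(ld2$d_prime, 0.99, tolerance = 0.05)
})

test_that("reference cohort has the study dimensions and frequencies", {
  sim <- simulate_reference_cohort(seed = 42)
  expect_equal(sum(sim$phenotypes$status == 1L), 369)
  expect_equal(sum(sim$phenotypes$status == 0L), 503)
  expect_equal(ncol(sim$genotypes$dosage), 22)
  sp <- split_by_status(sim$genotypes, sim$phenotypes)
  f <- allele_frequency(sp$control, "rs2066847")
  se <- sqrt(0.02 * 0.98 / (2 * 503))
  expect_lt(abs(f - 0.02), 3 * se)
  # determinism
  sim2 <- simulate_reference_cohort(seed = 42)
  expect_identical(sim$genotypes$dosage, sim2$genotypes$dosage)
})
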