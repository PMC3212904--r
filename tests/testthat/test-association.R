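test_that("allelic 2x2 test reproduces hand-computed Wald statistics", {
  null <- allelic_test(two_by_two(10, 90, 10, 90))
  expect_equal(null$or, 1)
  expect_equal(null$p_value, 1)

  r <- allelic_test(two_by_two(20, 80, 10, 90))
  expect_equal(r$or, 2.25)
  se <- sqrt(1 / 20 + 1 / 80 + 1 / 10 + 1 / 90)
  expect_equal(r$ci_low, exp(log(2.25) - 1.959964 * se), tolerance = 1e-6)
  expect_equal(round(r$ci_low, 2), 0.99)
  expect_equal(round(r$ci_high, 2), 5.09)

  expect_error(allelic_test(two_by_two(0, 0, 5, 5)), "margin")
})

test_that("zero cells trigger the flagged Haldane-Anscombe correction", {
  r <- allelic_test(two_by_two(5, 5, 0, 10))
  expect_true(r$haldane)
  expect_true(is.finite(r$ci_high))
  expect_equal(r$or, (5.5 * 10.5) / (5.5 * 0.5))
})

test_that("Wald p-value and CI agree about significance", {
  set.seed(29)
  for (i in 1:1000) {
    r <- allelic_test(random_table())
    excludes_one <- r$ci_low > 1 || r$ci_high < 1
    expect_identical(r$p_value < 0.05, excludes_one)
  }
})

test_that("carriage reduces to a dominant-coded 2x2 for one SNP", {
  set.seed(37)
  d <- rbinom(200, 2, 0.3)
  st <- rbinom(200, 1, plogis(-0.5 + 0.8 * (d >= 1)))
  gm <- make_gm(s = d)
  ph <- phenotype_vector(paste0("s", 1:200), st)
  carrier <- d >= 1
  tab <- two_by_two(sum(carrier & st == 1), sum(!carrier & st == 1),
                    sum(carrier & st == 0), sum(!carrier & st == 0))
  expect_equal(carriage_test(gm, ph, "s")$or, allelic_test(tab)$or)
  # dominant-coded logistic fit gives the same OR
  fit <- logistic_fit(cbind(dom = as.numeric(carrier)), st)
  expect_equal(exp(fit$coefficients[["dom"]]), carriage_test(gm, ph, "s")$or,
               tolerance = 1e-8)
})

test_that("compound exposure means two or more risk alleles overall", {
  gm <- make_gm(a = c(1L, 2L, 0L, 0L), b = c(1L, 0L, 1L, 0L))
  ph <- phenotype_vector(paste0("s", 1:4), c(1, 1, 0, 0))
  r <- compound_test(gm, ph, c("a", "b"))
  # s1 (1+1) and s2 (2+0) exposed; s3, s4 not
  expect_equal(r$table$a, 2); expect_equal(r$table$b, 0)
  expect_equal(r$table$c, 0); expect_equal(r$table$d, 2)
  expect_true(r$haldane)
  expect_true(is.finite(r$or))
})

test_that("samples missing at every listed SNP are excluded from exposure", {
  gm <- make_gm(a = c(1L, NA, 0L), b = c(0L, NA, 1L))
  ph <- phenotype_vector(paste0("s", 1:3), c(1, 1, 0))
  expect_message(r <- carriage_test(gm, ph, c("a", "b")), "excluded")
  expect_equal(r$table$a + r$table$b, 1)  # one case left
})

test_that("IRLS logistic regression matches glm", {
  set.seed(43)
  n <- 300
  X <- cbind(x1 = rnorm(n), x2 = rbinom(n, 2, 0.4))
  y <- rbinom(n, 1, plogis(-0.3 + 0.5 * X[, 1] - 0.4 * X[, 2]))
  fit <- logistic_fit(X, y)
  ref <- glm(y ~ X, family = binomial())
  expect_true(fit$converged)
  expect_equal(unname(fit$coefficients), unname(coef(ref)), tolerance = 1e-6)
  expect_equal(unname(fit$se),
               unname(sqrt(diag(vcov(ref)))), tolerance = 1e-4)
  expect_equal(fit$loglik, as.numeric(logLik(ref)), tolerance = 1e-8)
  expect_true(all(diff(fit$loglik_trace) >= -1e-9))
})

test_that("single binary covariate equals the closed-form 2x2 OR", {
  x <- rep(c(0, 1, 0, 1), c(20, 80, 10, 90))
  y <- c(rep(1, 100), rep(0, 100))
  fit <- logistic_fit(cbind(x = x), y)
  expect_equal(exp(fit$coefficients[["x"]]), (80 * 10) / (20 * 90),
               tolerance = 1e-8)
})

test_that("rank deficiency and separation are surfaced", {
  y <- rep(c(0, 1), 20)
  X <- cbind(z = rep(0, 40), w = rnorm(40))
  expect_error(logistic_fit(X, y), "z")
  # perfectly separating covariate
  x <- c(rep(0, 20), rep(1, 20))
  ysep <- c(rep(0, 20), rep(1, 20))
  fit <- suppressWarnings(logistic_fit(cbind(x = x), ysep))
  expect_true(fit$separated)
  expect_false(fit$converged)
  expect_warning(logistic_fit(cbind(x = x), ysep), "separation")
})

test_that("multivariate fit marks empty genotype cells inestimable", {
  set.seed(47)
  gm <- make_gm(common = rbinom(150, 2, 0.5),
                rare = rbinom(150, 1, 0.05))  # never 2 copies
  ph <- phenotype_vector(paste0("s", 1:150), rbinom(150, 1, 0.4))
  mv <- suppressMessages(multivariate_fit(gm, ph, coding = "genotype"))
  row <- mv$table[mv$table$term == "rare_2copy", ]
  expect_false(row$estimable)
  expect_true(is.na(row$or))
  expect_true(all(mv$table$estimable[mv$table$term == "common_1copy"]))
})

test_that("log-additive multivariate fit recovers a known effect", {
  set.seed(53)
  d1 <- rbinom(600, 2, 0.3); d2 <- rbinom(600, 2, 0.5)
  st <- rbinom(600, 1, plogis(-1 + log(2) * d1))
  gm <- make_gm(a = d1, b = d2)
  ph <- phenotype_vector(paste0("s", 1:600), st)
  mv <- multivariate_fit(gm, ph, coding = "log_additive")
  expect_equal(mv$table$or[1], 2, tolerance = 0.25)
  ref <- glm(st ~ d1 + d2, family = binomial())
  expect_equal(mv$table$or, unname(exp(coef(ref)[-1])), tolerance = 1e-6)
})

test_that("backward pruning keeps the truly associated SNP", {
  set.seed(59)
  d1 <- rbinom(800, 2, 0.3); d2 <- rbinom(800, 2, 0.5)
  st <- rbinom(800, 1, plogis(-1 + log(2.5) * d1))
  gm <- make_gm(a = d1, b = d2)
  ph <- phenotype_vector(paste0("s", 1:800), st)
  pruned <- backward_prune(gm, ph)
  expect_true("a" %in% pruned$snps)
})

test_that("analytic power behaves at the null and against simulation", {
  # at OR = 1 the one-tailed normal approximation returns alpha/2
  p0 <- power_allelic(369, 503, 0.59, 1)
  expect_equal(p0, 0.025, tolerance = 1e-6)
  # monotone in OR and n
  expect_gt(power_allelic(369, 503, 0.59, 1.5),
            power_allelic(369, 503, 0.59, 1.32))
  expect_gt(power_allelic(800, 800, 0.59, 1.32),
            power_allelic(369, 503, 0.59, 1.32))
  # simulation mode agrees within Monte-Carlo noise
  an <- power_allelic(200, 200, 0.3, 1.8)
  mc <- power_allelic(200, 200, 0.3, 1.8, method = "simulation",
                      n_rep = 500, seed = 61)
  expect_lt(abs(an - mc$power), 3 * mc$mc_se)
})

test_that("univariate scan reports frequencies and ORs per SNP", {
  sim <- simulate_cohort(cohort_config(
    variant_panel(c("a", "b"), control_raf = c(0.2, 0.5)),
    per_allele_or = c(3, 1), prevalence = 0.1,
    n_case = 400, n_control = 400, seed = 67))
  tab <- univariate_scan(sim$genotypes, sim$phenotypes)
  expect_equal(tab$snp_id, c("a", "b"))
  expect_gt(tab$or[1], 1.8)
  expect_equal(tab$or[2], 1, tolerance = 0.35)
  expect_true(all(tab$ci_low <= tab$or & tab$or <= tab$ci_high))
})
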