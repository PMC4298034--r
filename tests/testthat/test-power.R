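# GWAS power machinery: conditional allele frequencies, the allelic test,
# Monte Carlo power, and sample-size calculations.

test_that("case/control allele frequencies invert the penetrance model", {
  f <- case_control_allele_freqs(dc_model(c = 0.2))
  expect_equal(f$freq_cases, 0.60, tolerance = 1e-12)
  expect_equal(round(f$freq_controls, 5), 0.15556)
  expect_error(case_control_allele_freqs(dc_model(c = 0)),
               class = "dc_error_degenerate")
  # equal-frequency loci are exchangeable
  f2 <- case_control_allele_freqs(dc_model(n_loci = 2, prevalence = 0.1))
  expect_equal(f2$freq_cases[1], f2$freq_cases[2])
  expect_equal(f2$freq_controls[1], f2$freq_controls[2])
  # brute-force check: E[allele dose | phenotype] over all 3^n genotypes
  set.seed(13)
  cv <- runif(3, 0.05, 0.3)
  m <- dc_model(c = cv)
  e <- enumerate_genotypes(cv)
  p <- c(0, 0.25, 0.5)[apply(e$genotypes, 1, max) + 1]
  for (i in 1:3) {
    dose <- e$genotypes[, i] / 2
    expect_equal(case_control_allele_freqs(m)$freq_cases[i],
                 sum(e$probs * p * dose) / sum(e$probs * p), tolerance = 1e-12)
    expect_equal(case_control_allele_freqs(m)$freq_controls[i],
                 sum(e$probs * (1 - p) * dose) / sum(e$probs * (1 - p)),
                 tolerance = 1e-12)
  }
})

test_that("allelic chi-square matches the textbook statistic and chisq.test", {
  res <- allelic_chisq(30, 70, 10, 90)
  expect_equal(res$statistic, 12.5)
  expect_equal(res$p_value, stats::pchisq(12.5, 1, lower.tail = FALSE))
  eq <- allelic_chisq(25, 75, 25, 75)
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p_value, 1)
  zm <- allelic_chisq(0, 100, 0, 50)
  expect_equal(zm$statistic, 0)
  expect_true(zm$zero_margin)
  set.seed(2)
  for (i in 1:20) {
    tab <- matrix(rpois(4, 40) + 1, 2)
    ours <- allelic_chisq(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])
    ref <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
  }
  expect_error(allelic_chisq(-1, 2, 3, 4), class = "dc_error_invalid_parameter")
})

test_that("Monte Carlo power behaves at the design boundaries", {
  m <- dc_model(c = 0.2)
  p1 <- gwas_power_mc(m, study_design(375, 3375, alpha = 1), 500, seed = 1)
  expect_equal(p1$any_locus_power, 1)
  tiny <- gwas_power_mc(m, study_design(10, 10), 2e4, seed = 2)
  expect_lt(tiny$any_locus_power, 0.01)
  # with one locus, any-locus power equals the per-locus power
  one <- gwas_power_mc(m, study_design(200, 1800, alpha = 1e-4), 5e3, seed = 3)
  expect_equal(one$any_locus_power, one$per_locus$power[1])
})

test_that("power is monotone in sample size, threshold and tagging", {
  m <- dc_model(n_loci = 2, prevalence = 0.1)
  pow <- function(cases, controls, alpha, r2) {
    gwas_power_mc(m, study_design(cases, controls, alpha = alpha, tagging_r2 = r2),
                  4e3, seed = 99)$any_locus_power
  }
  expect_lte(pow(100, 900, 1e-5, 1), pow(400, 3600, 1e-5, 1))
  expect_lte(pow(400, 3600, 1e-7, 1), pow(400, 3600, 1e-4, 1))
  expect_lte(pow(400, 3600, 1e-5, 0.3), pow(400, 3600, 1e-5, 1))
  # any-locus power dominates each per-locus power
  res <- gwas_power_mc(m, study_design(300, 2700, alpha = 1e-5), 4e3, seed = 4)
  expect_true(all(res$any_locus_power >= res$per_locus$power))
})

test_that("Monte Carlo power agrees with the normal-approximation oracle", {
  m <- dc_model(c = 0.2)
  # moderate-power design so the comparison is informative
  design <- study_design(2000, 18000, alpha = 5e-8, tagging_r2 = 0.008)
  res <- gwas_power_mc(m, design, 4e4, seed = 55)
  f <- case_control_allele_freqs(m)
  pooled <- (2 * 2000 * f$freq_cases + 2 * 18000 * f$freq_controls) / (2 * 20000)
  shrink <- sqrt(design$tagging_r2)
  f1 <- pooled + shrink * (f$freq_cases - pooled)
  f2 <- pooled + shrink * (f$freq_controls - pooled)
  expected <- oracle_power_normal(f1, f2, 2 * 2000, 2 * 18000, design$alpha)
  mc_se <- sqrt(expected * (1 - expected) / 4e4)
  expect_gt(expected, 0.1)
  expect_lt(expected, 0.9)
  expect_lt(abs(res$any_locus_power - expected), 3 * mc_se)
})

test_that("two-proportion sample sizes reproduce the pooled-variance formula", {
  expect_identical(sample_size_two_proportions(0.0782, 0.0852), 24034L)
  expect_identical(sample_size_two_proportions(0.14, 0.1503), 18359L)
  expect_identical(sample_size_two_proportions(0.0852, 0.0782),
                   sample_size_two_proportions(0.0782, 0.0852))
  expect_error(sample_size_two_proportions(0.1, 0.1),
               class = "dc_error_no_solution")
  # asymptotic (p1 - p2)^-2 scaling: halving the gap ~quadruples the size
  n1 <- sample_size_two_proportions(0.10, 0.11)
  n2 <- sample_size_two_proportions(0.10, 0.105)
  expect_equal(n2 / n1, 4, tolerance = 0.05)
})

test_that("genome-wide thresholds are Bonferroni corrections", {
  expect_equal(genomewide_threshold(1e6, 0.05), 5e-8)
  expect_equal(genomewide_threshold(1, 0.05), 0.05)
  expect_equal(genomewide_threshold(20, 0.05), 0.0025)
})

test_that("power results expose tidy and glance summaries", {
  m <- dc_model(n_loci = 2, prevalence = 0.1)
  res <- gwas_power_mc(m, study_design(300, 2700), 1e3, seed = 6)
  td <- tidy(res)
  expect_equal(nrow(td), 2)
  expect_named(td, c("locus", "power", "ci_halfwidth"))
  gl <- glance(res)
  expect_equal(gl$n_loci, 2)
  expect_equal(gl$any_locus_power, res$any_locus_power)
})
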