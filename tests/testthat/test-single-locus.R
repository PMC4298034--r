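# Exact single-locus algebra: genotype distributions, prevalence, families,
# twins and language lateralization.

test_that("Hardy-Weinberg genotype distributions are correct and normalized", {
  expect_equal(hwe_genotypes(0.2)$prob, c(0.64, 0.32, 0.04))
  expect_equal(hwe_genotypes(0)$prob, c(1, 0, 0))
  expect_equal(hwe_genotypes(1)$prob, c(0, 0, 1))
  for (c in seq(0, 1, by = 0.1)) {
    expect_equal(sum(hwe_genotypes(c)$prob), 1, tolerance = 1e-12)
  }
  expect_error(hwe_genotypes(1.2), class = "dc_error_invalid_parameter")
  expect_error(hwe_genotypes(-0.1), class = "dc_error_invalid_parameter")
})

test_that("population prevalence follows the closed form c/2 for the default model", {
  expect_equal(population_left_rate(dc_model(c = 0.2)), 0.10)
  expect_equal(population_left_rate(dc_model(c = 0.4)), 0.20)
  expect_equal(population_left_rate(dc_model(c = 0)), 0)
  for (c in seq(0.05, 0.95, by = 0.1)) {
    expect_equal(population_left_rate(dc_model(c = c)), c / 2, tolerance = 1e-12)
  }
  # non-default penetrances: plain expectation over HWE genotypes
  pen <- penetrance(0.1, 0.3, 0.9)
  expect_equal(
    population_left_rate(dc_model(c = 0.3, penetrance = pen)),
    sum(hwe_genotypes(0.3)$prob * as.numeric(pen))
  )
})

test_that("genotype posterior given handedness matches Bayes inversion", {
  m <- dc_model(c = 0.2)
  expect_equal(genotype_given_hand(m, "L")$prob, c(0, 0.8, 0.2))
  expect_equal(genotype_given_hand(m, "R")$prob,
               c(0.64, 0.24, 0.02) / 0.9, tolerance = 1e-12)
  expect_equal(sum(genotype_given_hand(m, "L")$prob), 1, tolerance = 1e-12)
  # a model in which nobody is left-handed cannot be conditioned on "L"
  m0 <- dc_model(c = 0.2, penetrance = penetrance(0, 0, 0))
  expect_error(genotype_given_hand(m0, "L"), class = "dc_error_degenerate")
})

test_that("offspring left-handedness by parental phenotype matches enumeration", {
  m <- dc_model(c = 0.2)
  expect_equal(offspring_left_rate(m, "RxR"), 0.07778, tolerance = 1e-4)
  expect_equal(offspring_left_rate(m, "RxL"), 0.18889, tolerance = 1e-4)
  expect_equal(offspring_left_rate(m, "LxL"), 0.30, tolerance = 1e-12)
  # monotone in the number of left-handed parents across the frequency range
  for (c in seq(0.05, 0.95, by = 0.15)) {
    p <- family_predictions(dc_model(c = c))$p_left
    expect_true(p[1] <= p[2] && p[2] <= p[3])
  }
  expect_error(offspring_left_rate(dc_model(c = 0), "LxL"),
               class = "dc_error_degenerate")
})

test_that("MZ twin pair distribution matches shared-genotype algebra", {
  m <- dc_model(c = 0.2)
  expect_equal(twin_distribution(m, "MZ")$prob, c(0.83, 0.14, 0.03),
               tolerance = 1e-12)
  expect_equal(twin_distribution(m, "MZ", genotype = "CC")$prob,
               c(0.25, 0.5, 0.25))
  expect_equal(twin_distribution(m, "MZ", genotype = "DC")$prob,
               c(9, 6, 1) / 16)
  expect_equal(twin_distribution(dc_model(c = 0), "MZ")$prob, c(1, 0, 0))
})

test_that("DZ twin pair distribution equals the mating-type enumeration oracle", {
  m <- dc_model(c = 0.2)
  dz <- twin_distribution(m, "DZ")$prob
  expect_equal(dz[2], 0.16, tolerance = 1e-12)
  expect_equal(dz[3], 0.02, tolerance = 1e-12)
  expect_equal(dz, unname(oracle_dz_single_locus(0.2)), tolerance = 1e-12)
  expect_equal(twin_distribution(dc_model(c = 0), "DZ")$prob, c(1, 0, 0))
  set.seed(11)
  for (i in 1:10) {
    c <- runif(1)
    pen <- random_penetrance()
    mm <- dc_model(c = c, penetrance = penetrance(pen[1], pen[2], pen[3]))
    expect_equal(twin_distribution(mm, "DZ")$prob,
                 unname(oracle_dz_single_locus(c, pen)), tolerance = 1e-12)
  }
})

test_that("MZ discordance never exceeds DZ discordance", {
  set.seed(7)
  for (i in 1:25) {
    pen <- stats::runif(3) # deliberately unordered
    m <- dc_model(c = runif(1), penetrance = penetrance(pen[1], pen[2], pen[3]))
    mz <- twin_distribution(m, "MZ")$prob[2]
    dz <- twin_distribution(m, "DZ")$prob[2]
    expect_lte(mz, dz + 1e-12)
  }
})

test_that("twin distributions conditioned on parental handedness", {
  m <- dc_model(c = 0.2)
  expect_equal(twin_distribution(m, "MZ", parents = "LxL")$prob[2], 0.36,
               tolerance = 1e-12)
  expect_lt(twin_distribution(m, "MZ", parents = "RxR")$prob[2], 0.14)
  expect_equal(twin_distribution(dc_model(c = 0), "MZ", parents = "RxR")$prob,
               c(1, 0, 0))
  # discordance increases with the number of left-handed parents
  d <- vapply(c("RxR", "RxL", "LxL"),
              function(p) twin_distribution(m, "MZ", parents = p)$prob[2],
              numeric(1))
  expect_true(d[["RxR"]] < d[["RxL"]] && d[["RxL"]] < d[["LxL"]])
  expect_error(twin_distribution(dc_model(c = 0), "DZ", parents = "LxL"),
               class = "dc_error_degenerate")
})

test_that("lateralization table has consistent joint, conditionals and margins", {
  m <- dc_model(c = 0.2)
  lat <- lateralization_table(m)
  expect_equal(sum(lat$joint$prob), 1, tolerance = 1e-12)
  cond <- setNames(lat$conditional$p_rightlang_given_hand, lat$conditional$hand)
  expect_equal(round(cond[["R"]], 3), 0.078)
  expect_equal(cond[["L"]], 0.30, tolerance = 1e-12)
  expect_equal(
    lat$joint$prob[lat$joint$hand == "L" & lat$joint$language == "right"],
    0.03, tolerance = 1e-12
  )
  # marginal handedness equals the population rate; with shared penetrances
  # the marginal right-language rate does too
  for (c in c(0.1, 0.2, 0.5, 0.9)) {
    mm <- dc_model(c = c)
    ll <- lateralization_table(mm)
    expect_equal(sum(ll$joint$prob[ll$joint$hand == "L"]),
                 population_left_rate(mm), tolerance = 1e-12)
    expect_equal(sum(ll$joint$prob[ll$joint$language == "right"]),
                 population_left_rate(mm), tolerance = 1e-12)
  }
  # conditionals recompute from the joint by exact division
  joint <- lat$joint
  pR <- sum(joint$prob[joint$hand == "R"])
  expect_equal(cond[["R"]],
               joint$prob[joint$hand == "R" & joint$language == "right"] / pR)
})

test_that("all returned distributions are normalized across random models", {
  set.seed(3)
  for (i in 1:10) {
    pen <- random_penetrance()
    m <- dc_model(c = runif(1, 0.05, 0.95),
                  penetrance = penetrance(pen[1], pen[2], pen[3]))
    expect_equal(sum(genotype_given_hand(m, "L")$prob), 1, tolerance = 1e-12)
    expect_equal(sum(twin_distribution(m, "MZ")$prob), 1, tolerance = 1e-12)
    expect_equal(sum(twin_distribution(m, "DZ")$prob), 1, tolerance = 1e-12)
    expect_equal(sum(twin_distribution(m, "DZ", parents = "RxL")$prob), 1,
                 tolerance = 1e-12)
    expect_equal(sum(lateralization_table(m)$joint$prob), 1, tolerance = 1e-12)
  }
})
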