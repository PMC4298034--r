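# Monte Carlo simulation of nuclear families and twin pairs.
#
# The simulator composes the same primitives as sample_genotypes() and
# meiosis() — per-locus Hardy-Weinberg founder draws, uniform allele
# transmission, damage-rule phenotypes — but iterates over loci rather than
# families, carrying a running genotype-class maximum per individual. That
# keeps memory at O(replicates) and cost at O(replicates * n_loci) vector
# operations, which is what makes 10^6-replicate runs of 1000-locus models
# practical in R.

sim_classes_family <- function(replicates, c_values, n_offspring = 1) {
  m <- replicates
  cl1 <- cl2 <- integer(m)
  clo <- replicate(n_offspring, integer(m), simplify = FALSE)
  for (ci in c_values) {
    q1 <- (1 - ci)^2
    q2 <- 1 - ci^2
    u1 <- stats::runif(m)
    u2 <- stats::runif(m)
    g1 <- (u1 > q1) + (u1 > q2)
    g2 <- (u2 > q1) + (u2 > q2)
    cl1 <- pmax(cl1, g1)
    cl2 <- pmax(cl2, g2)
    for (k in seq_len(n_offspring)) {
      go <- (stats::runif(m) < g1 / 2) + (stats::runif(m) < g2 / 2)
      clo[[k]] <- pmax(clo[[k]], go)
    }
  }
  list(parent1 = cl1, parent2 = cl2, offspring = clo)
}

sim_phenotypes <- function(classes, pen) {
  stats::runif(length(classes)) < pen[classes + 1]
}

#' Binomial confidence-interval half-width
#'
#' Normal-approximation 95% half-width `1.96 * sqrt(p(1-p)/m)` used
#' throughout the simulation reports.
#'
#' @param p Estimated proportion(s).
#' @param m Number of replicates behind each estimate.
#' @return Half-width(s) on the probability scale (`NA` where `p` is `NA`).
#' @examples
#' ci_halfwidth(0.085, 1e6)
#' @export
ci_halfwidth <- function(p, m) {
  if (!is.numeric(p) || !is.numeric(m) || any(m < 1, na.rm = TRUE)) {
    stop_invalid("`p` must be numeric and `m` >= 1.")
  }
  1.96 * sqrt(p * (1 - p) / m)
}

#' Simulate nuclear families under a DC model
#'
#' For each replicate, two parents are drawn under per-locus Hardy-Weinberg
#' proportions, each parent's phenotype is drawn from its damage-rule
#' penetrance, one offspring is produced by independent Mendelian
#' segregation at every locus, and the offspring's phenotype is drawn from
#' its penetrance. Replicates are then stratified by the realized parental
#' phenotype pairing (so stratum sizes vary as they would in a cohort), and
#' the proportion of left-handed offspring is reported per stratum with a
#' normal-approximation 95% CI. A stratum with no simulated families (for
#' example `LxL` when all `c = 0`) is reported as undefined (`NA`) rather
#' than as 0%.
#'
#' @param model A [dc_model()].
#' @param replicates Number of simulated families.
#' @param seed Optional integer seed for reproducibility.
#' @return A `dc_family_sim` tibble with columns `parents`, `n_families`,
#'   `n_left_offspring`, `p_left`, `ci_halfwidth` and `estimate_defined`,
#'   with the model, seed, replicate count and overall offspring
#'   left-handedness rate stored as attributes.
#' @examples
#' simulate_families(dc_model(c = 0.2), replicates = 1e4, seed = 1)
#' @export
simulate_families <- function(model, replicates = 1e6, seed = NULL) {
  check_model(model)
  replicates <- check_count(replicates, "replicates")
  pen <- as.numeric(model$penetrance)
  res <- with_seed(seed, {
    cls <- sim_classes_family(replicates, model$c)
    ph1 <- sim_phenotypes(cls$parent1, pen)
    ph2 <- sim_phenotypes(cls$parent2, pen)
    pho <- sim_phenotypes(cls$offspring[[1]], pen)
    stratum <- factor(ph1 + ph2, levels = 0:2, labels = PARENT_LABELS)
    n_fam <- as.integer(table(stratum))
    n_left <- as.integer(tapply(pho, stratum, sum, default = 0L))
    list(n_fam = n_fam, n_left = n_left, overall = mean(pho))
  })
  p_left <- ifelse(res$n_fam > 0, res$n_left / res$n_fam, NA_real_)
  out <- tibble::tibble(
    parents = PARENT_LABELS,
    n_families = res$n_fam,
    n_left_offspring = res$n_left,
    p_left = p_left,
    ci_halfwidth = ifelse(res$n_fam > 0, ci_halfwidth(p_left, pmax(res$n_fam, 1)), NA_real_),
    estimate_defined = res$n_fam > 0
  )
  structure(out,
    class = c("dc_family_sim", class(out)),
    model = model, seed = seed, replicates = replicates,
    offspring_left_rate = res$overall
  )
}

#' Simulate twin pairs under a DC model
#'
#' Monozygotic pairs share a single genotype drawn under Hardy-Weinberg
#' proportions and draw two phenotypes independently given it. Dizygotic
#' pairs are full siblings: two random-mating parents are drawn and each
#' twin receives an independent Mendelian genotype, phenotypes again being
#' independent given genotype.
#'
#' @param model A [dc_model()].
#' @param zygosity `"MZ"` or `"DZ"`.
#' @param replicates Number of simulated pairs.
#' @param seed Optional integer seed.
#' @return A `dc_twin_sim` tibble with columns `zygosity`, `pair`,
#'   `n_pairs`, `proportion` and `ci_halfwidth`.
#' @examples
#' simulate_twins(dc_model(c = 0.2), "MZ", replicates = 1e4, seed = 1)
#' @export
simulate_twins <- function(model, zygosity = c("MZ", "DZ"), replicates = 1e6,
                           seed = NULL) {
  check_model(model)
  zygosity <- match_arg_checked(zygosity, c("MZ", "DZ"), "zygosity")
  replicates <- check_count(replicates, "replicates")
  pen <- as.numeric(model$penetrance)
  counts <- with_seed(seed, {
    if (zygosity == "MZ") {
      m <- replicates
      cl <- integer(m)
      for (ci in model$c) {
        u <- stats::runif(m)
        cl <- pmax(cl, (u > (1 - ci)^2) + (u > 1 - ci^2))
      }
      t1 <- sim_phenotypes(cl, pen)
      t2 <- sim_phenotypes(cl, pen)
    } else {
      cls <- sim_classes_family(replicates, model$c, n_offspring = 2)
      t1 <- sim_phenotypes(cls$offspring[[1]], pen)
      t2 <- sim_phenotypes(cls$offspring[[2]], pen)
    }
    tabulate(t1 + t2 + 1L, nbins = 3)
  })
  prop <- counts / replicates
  out <- tibble::tibble(
    zygosity = zygosity,
    pair = PAIR_LABELS,
    n_pairs = as.integer(counts),
    proportion = prop,
    ci_halfwidth = ci_halfwidth(prop, replicates)
  )
  structure(out,
    class = c("dc_twin_sim", class(out)),
    model = model, seed = seed, replicates = replicates
  )
}

#' Reproduce the family-and-twin prediction table across locus counts
#'
#' For each entry of `n_loci`, solves the equal-frequency prevalence
#' equation at the target prevalence, simulates families and monozygotic
#' twin pairs, and tabulates the six headline cells: percent left-handed
#' offspring of `RxR`, `RxL` and `LxL` parents and the percent of `R-R`,
#' `R-L` and `L-L` MZ pairs. Exact analytic values (computed by enumeration)
#' are included alongside each Monte Carlo estimate.
#'
#' @param n_loci Integer vector of locus counts.
#' @param prevalence Target population rate of the atypical phenotype.
#' @param replicates Simulated families (and, separately, twin pairs) per row.
#' @param seed Optional integer seed for the whole run.
#' @param penetrance A [penetrance()] triple.
#' @param simulate If `FALSE`, only the analytic columns are computed.
#' @return A `dc_table2` tibble in long form: one row per (locus count,
#'   cell), with columns `n_loci`, `c`, `panel` (`"family"` or
#'   `"mz_twin"`), `cell`, `analytic`, and when simulating `estimate`,
#'   `ci_halfwidth` and `n` (the replicate or stratum count behind the
#'   estimate).
#' @examples
#' reproduce_table2(c(1, 2), replicates = 1e4, seed = 1)
#' reproduce_table2(c(1, 10, 100), simulate = FALSE)
#' @export
reproduce_table2 <- function(n_loci = c(1, 2, 3, 4, 5, 10, 20, 50, 100, 200, 500, 1000),
                             prevalence = 0.1, replicates = 1e6, seed = NULL,
                             penetrance = dcmodel::penetrance(),
                             simulate = TRUE) {
  if (length(n_loci) < 1) stop_invalid("`n_loci` must be non-empty.")
  pen <- as_penetrance(penetrance)
  run <- function() {
    purrr::map_dfr(n_loci, function(n) {
      model <- dc_model(n_loci = n, prevalence = prevalence, penetrance = pen)
      fam_an <- family_predictions(model)$p_left
      mz_an <- twin_distribution(model, "MZ")$prob
      base <- tibble::tibble(
        n_loci = n,
        c = model$c[[1]],
        panel = rep(c("family", "mz_twin"), each = 3),
        cell = c(PARENT_LABELS, PAIR_LABELS),
        analytic = c(fam_an, mz_an)
      )
      if (!simulate) return(base)
      fam <- simulate_families(model, replicates)
      mz <- simulate_twins(model, "MZ", replicates)
      base$estimate <- c(fam$p_left, mz$proportion)
      base$ci_halfwidth <- c(fam$ci_halfwidth, mz$ci_halfwidth)
      base$n <- c(fam$n_families, mz$n_pairs * 0L + replicates)
      base
    })
  }
  out <- with_seed(seed, run())
  structure(out,
    class = c("dc_table2", class(out)),
    prevalence = prevalence, replicates = if (simulate) replicates else NA_integer_,
    seed = seed
  )
}
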