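#' Case-control GWAS study design
#'
#' @param n_cases Number of cases (left-handers).
#' @param n_controls Number of controls (right-handers).
#' @param alpha Per-test significance threshold; the default `5e-8` is the
#'   conventional genome-wide level (0.05 Bonferroni-corrected for one
#'   million tests, see [genomewide_threshold()]).
#' @param tagging_r2 Linkage-disequilibrium r-squared between the genotyped
#'   marker and the causal locus; 1 means the marker is the causal locus.
#'   Values below 1 attenuate the case-control allele-frequency difference
#'   by `sqrt(tagging_r2)`.
#' @return A `dc_design` object.
#' @examples
#' study_design(375, 3375)
#' study_design(2350, 21093)  # the ENGAGE meta-analysis design
#' @export
study_design <- function(n_cases, n_controls, alpha = 5e-8, tagging_r2 = 1) {
  n_cases <- check_count(n_cases, "n_cases", min = 0)
  n_controls <- check_count(n_controls, "n_controls", min = 0)
  if (!is.numeric(alpha) || length(alpha) != 1 || is.na(alpha) ||
      alpha <= 0 || alpha > 1) {
    stop_invalid("`alpha` must be in (0, 1].")
  }
  check_probability(tagging_r2, "tagging_r2", 1)
  structure(
    list(n_cases = n_cases, n_controls = n_controls,
         alpha = alpha, tagging_r2 = tagging_r2),
    class = "dc_design"
  )
}

#' @export
print.dc_design <- function(x, ...) {
  cat(sprintf("<dc_design>  %d cases / %d controls, alpha = %g, tagging r2 = %g\n",
              x$n_cases, x$n_controls, x$alpha, x$tagging_r2))
  invisible(x)
}

check_design <- function(design) {
  if (!inherits(design, "dc_design")) {
    stop_invalid("`design` must be a `study_design()` object.")
  }
  invisible(design)
}

#' Chance-allele frequencies in cases and controls
#'
#' Inverts the penetrance model by Bayes' rule: given that an individual is
#' left-handed (a case) or right-handed (a control), what is the expected
#' frequency of the chance allele at each locus? Computed exactly from the
#' locus-marginal genotype distribution combined with the damage-rule class
#' of the remaining loci (loci are independent, so the marginal is exact for
#' any number of loci). For the default single-locus model at 10%
#' prevalence the frequency is 0.60 in cases and 0.15556 in controls.
#'
#' @param model A [dc_model()].
#' @return A tibble with one row per locus: `locus`, `c`, `freq_cases`,
#'   `freq_controls`.
#' @examples
#' case_control_allele_freqs(dc_model(c = 0.2))
#' @export
case_control_allele_freqs <- function(model) {
  check_model(model)
  prev <- population_left_rate(model)
  if (prev <= 0 || prev >= 1) {
    stop_degenerate("Both phenotypes must have positive probability to condition on them.")
  }
  pen <- as.numeric(model$penetrance)
  purrr::map_dfr(seq_len(model$n_loci), function(i) {
    gi <- locus_genotype_probs(model$c[[i]])
    other <- class_pmf(model$c[-i])
    fL <- 0; fR <- 0
    for (a in 1:3) {
      p_left <- sum(other * pen[pmax(a, 1:3)])
      af <- (a - 1) / 2
      fL <- fL + gi[a] * p_left * af
      fR <- fR + gi[a] * (1 - p_left) * af
    }
    tibble::tibble(
      locus = i, c = model$c[[i]],
      freq_cases = fL / prev, freq_controls = fR / (1 - prev)
    )
  })
}

#' Allelic chi-square association test
#'
#' The standard 1-df allelic test on a 2x2 table of allele counts, without
#' continuity correction. Vectorized over tables so it can score millions of
#' simulated studies. A table with a zero margin is flagged and scored as
#' statistic 0, p = 1.
#'
#' @param cases_c,cases_d Chance- and dextral-allele counts among case
#'   alleles (2 per individual).
#' @param controls_c,controls_d The same among control alleles.
#' @return A tibble with columns `statistic`, `p_value` and `zero_margin`.
#' @examples
#' allelic_chisq(30, 70, 10, 90)  # statistic 12.5
#' @export
allelic_chisq <- function(cases_c, cases_d, controls_c, controls_d) {
  counts <- cbind(cases_c, cases_d, controls_c, controls_d)
  if (!is.numeric(counts) || anyNA(counts) || any(counts < 0)) {
    stop_invalid("Allele counts must be non-negative numbers.")
  }
  if (any(rowSums(counts) == 0)) stop_invalid("Each table must have a positive total.")
  stat <- chisq_stat(cases_c, cases_d, controls_c, controls_d)
  zero <- (cases_c + cases_d == 0) | (controls_c + controls_d == 0) |
    (cases_c + controls_c == 0) | (cases_d + controls_d == 0)
  tibble::tibble(
    statistic = stat,
    p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
    zero_margin = zero
  )
}

# bare vectorized statistic for the Monte Carlo loop
chisq_stat <- function(a, b, c, d) {
  n <- a + b + c + d
  denom <- (a + b) * (c + d) * (a + c) * (b + d)
  stat <- ifelse(denom > 0, n * (a * d - b * c)^2 / denom, 0)
  as.numeric(stat)
}

#' Monte Carlo GWAS power under a DC model
#'
#' Estimates the power of a case-control GWAS to detect the model's loci at
#' a given significance threshold. Each replicate draws case and control
#' chance-allele counts at every locus from binomial distributions at the
#' exact case/control allele frequencies (see
#' [case_control_allele_freqs()]), optionally attenuated toward the pooled
#' frequency when `tagging_r2 < 1`, and scores each locus with the allelic
#' chi-square test. Per-locus power is the fraction of replicates in which
#' that locus is significant; any-locus power the fraction in which at least
#' one locus is.
#'
#' @param model A [dc_model()].
#' @param design A [study_design()].
#' @param replicates Number of simulated studies.
#' @param seed Optional integer seed.
#' @return A `dc_power` object; see [tidy.dc_power()] and
#'   [glance.dc_power()].
#' @examples
#' gwas_power_mc(dc_model(c = 0.2), study_design(375, 3375),
#'               replicates = 1000, seed = 1)
#' @export
gwas_power_mc <- function(model, design, replicates = 1e5, seed = NULL) {
  check_model(model)
  check_design(design)
  replicates <- check_count(replicates, "replicates")
  if (design$n_cases < 1 || design$n_controls < 1) {
    stop_invalid("Power estimation needs at least one case and one control.")
  }
  freqs <- case_control_allele_freqs(model)
  n1 <- 2 * design$n_cases
  n2 <- 2 * design$n_controls
  pooled <- (n1 * freqs$freq_cases + n2 * freqs$freq_controls) / (n1 + n2)
  shrink <- sqrt(design$tagging_r2)
  f1 <- pooled + shrink * (freqs$freq_cases - pooled)
  f2 <- pooled + shrink * (freqs$freq_controls - pooled)
  crit <- stats::qchisq(design$alpha, df = 1, lower.tail = FALSE)
  res <- with_seed(seed, {
    any_sig <- rep(FALSE, replicates)
    per_locus <- numeric(model$n_loci)
    for (i in seq_len(model$n_loci)) {
      a <- stats::rbinom(replicates, n1, f1[[i]])
      cc <- stats::rbinom(replicates, n2, f2[[i]])
      sig <- chisq_stat(a, n1 - a, cc, n2 - cc) > crit
      per_locus[i] <- mean(sig)
      any_sig <- any_sig | sig
    }
    list(per_locus = per_locus, any = mean(any_sig))
  })
  structure(
    list(
      per_locus = tibble::tibble(
        locus = seq_len(model$n_loci),
        power = res$per_locus,
        ci_halfwidth = ci_halfwidth(res$per_locus, replicates)
      ),
      any_locus_power = res$any,
      any_ci_halfwidth = ci_halfwidth(res$any, replicates),
      replicates = replicates,
      design = design, model = model, seed = seed
    ),
    class = "dc_power"
  )
}

#' @export
print.dc_power <- function(x, ...) {
  cat(sprintf("<dc_power>  %d simulated studies, %d cases / %d controls, alpha = %g\n",
              x$replicates, x$design$n_cases, x$design$n_controls, x$design$alpha))
  cat(sprintf("  any-locus power: %.4f (+/- %.4f)\n",
              x$any_locus_power, x$any_ci_halfwidth))
  cat("  per-locus power: ",
      paste(sprintf("%.4f", utils::head(x$per_locus$power, 8)), collapse = " "),
      if (nrow(x$per_locus) > 8) " ..." else "", "\n", sep = "")
  invisible(x)
}

#' Tidiers for Monte Carlo power results
#'
#' @param x A `dc_power` object from [gwas_power_mc()].
#' @param ... Unused.
#' @return `tidy()` returns the per-locus power table; `glance()` a one-row
#'   summary including the any-locus power and the design.
#' @export
tidy.dc_power <- function(x, ...) x$per_locus

#' @rdname tidy.dc_power
#' @export
glance.dc_power <- function(x, ...) {
  tibble::tibble(
    n_loci = x$model$n_loci,
    any_locus_power = x$any_locus_power,
    ci_halfwidth = x$any_ci_halfwidth,
    max_per_locus_power = max(x$per_locus$power),
    replicates = x$replicates,
    n_cases = x$design$n_cases,
    n_controls = x$design$n_controls,
    alpha = x$design$alpha,
    tagging_r2 = x$design$tagging_r2
  )
}

#' Sample size to distinguish two proportions
#'
#' Per-group sample size for a two-sided two-proportion comparison using the
#' pooled-variance normal approximation without continuity correction:
#' \deqn{N = \frac{\left(z_{1-\alpha/2}\sqrt{2\bar p(1-\bar p)} +
#'   z_{power}\sqrt{p_1(1-p_1) + p_2(1-p_2)}\right)^2}{(p_1-p_2)^2},
#'   \quad \bar p = (p_1+p_2)/2,}
#' rounded to the nearest integer. Distinguishing 7.82% from 8.52%
#' left-handed offspring at 5% significance and 80% power gives 24,034
#' pairs; 14% versus 15.03% MZ discordance gives 18,359.
#'
#' @param p1,p2 The two proportions, strictly between 0 and 1 and unequal.
#' @param alpha Two-sided significance level.
#' @param power Desired power.
#' @return The per-group sample size (integer).
#' @examples
#' sample_size_two_proportions(0.0782, 0.0852)  # 24034
#' sample_size_two_proportions(0.14, 0.1503)    # 18359
#' @export
sample_size_two_proportions <- function(p1, p2, alpha = 0.05, power = 0.80) {
  check_probability(p1, "p1", 1)
  check_probability(p2, "p2", 1)
  if (p1 <= 0 || p1 >= 1 || p2 <= 0 || p2 >= 1) {
    stop_invalid("`p1` and `p2` must be strictly inside (0, 1).")
  }
  check_probability(alpha, "alpha", 1)
  check_probability(power, "power", 1)
  if (p1 == p2) {
    stop_no_solution("`p1` and `p2` are equal; no finite sample size distinguishes them.")
  }
  pbar <- (p1 + p2) / 2
  z_a <- stats::qnorm(1 - alpha / 2)
  z_b <- stats::qnorm(power)
  num <- (z_a * sqrt(2 * pbar * (1 - pbar)) +
            z_b * sqrt(p1 * (1 - p1) + p2 * (1 - p2)))^2
  as.integer(round(num / (p1 - p2)^2))
}

#' Bonferroni genome-wide significance threshold
#'
#' @param n_tests Number of independent tests (for a GWAS, conventionally
#'   one million possible loci).
#' @param family_alpha Family-wise error rate.
#' @return The per-test threshold `family_alpha / n_tests`.
#' @examples
#' genomewide_threshold(1e6)  # 5e-8
#' @export
genomewide_threshold <- function(n_tests, family_alpha = 0.05) {
  n_tests <- check_count(n_tests, "n_tests")
  check_probability(family_alpha, "family_alpha", 1)
  family_alpha / n_tests
}
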