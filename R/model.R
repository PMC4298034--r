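#' Penetrance triple of the dextral-chance model
#'
#' A penetrance model maps the three genotype classes at a dextral/chance
#' locus to the probability of the atypical phenotype (left-handedness, or
#' right-hemisphere language dominance). The defaults are the classical DC
#' model values: `DD` individuals are never left-handed, heterozygotes are
#' left-handed with probability 1/4 and `CC` homozygotes with probability
#' 1/2. The `CC` probability of 1/2 encodes "deep chance": phenotype is
#' irreducibly random given genotype, so co-twins and pleiotropic traits are
#' independent conditional on genotype.
#'
#' @param dd,dc,cc Probability of the atypical phenotype for the `DD`, `DC`
#'   and `CC` genotype classes. Each must lie in `[0, 1]`.
#' @return A `dc_penetrance` object: a named numeric vector of length 3.
#' @examples
#' penetrance()            # the standard DC model: 0, 0.25, 0.5
#' penetrance(0, 0.3, 0.6) # a steeper variant
#' @export
penetrance <- function(dd = 0, dc = 0.25, cc = 0.5) {
  check_probability(dd, "dd", 1)
  check_probability(dc, "dc", 1)
  check_probability(cc, "cc", 1)
  structure(c(DD = dd, DC = dc, CC = cc), class = "dc_penetrance")
}

as_penetrance <- function(x, what = "penetrance") {
  if (inherits(x, "dc_penetrance")) return(x)
  if (is.numeric(x) && length(x) == 3) return(penetrance(x[[1]], x[[2]], x[[3]]))
  stop_invalid(sprintf("`%s` must be a dc_penetrance or a numeric vector of length 3.", what))
}

#' @export
print.dc_penetrance <- function(x, ...) {
  cat("<dc_penetrance>  P(atypical | genotype)\n")
  print(setNames(as.numeric(x), GENOTYPE_LABELS))
  invisible(x)
}

#' Specify a dextral-chance model
#'
#' Constructs a single-locus (`n_loci = 1`) or multilocus DC model. Each
#' locus carries a dextral allele `D` and a chance allele `C`; genotype
#' classes combine across loci by the damage rule (see
#' [damage_rule_penetrance()]): homozygosity `CC` at any locus places an
#' individual in the highest penetrance class, otherwise heterozygosity at
#' any locus places it in the middle class, otherwise in the baseline class.
#' With `n_loci = 1` this is exactly the classical single-locus model.
#'
#' Either `c` (per-locus chance-allele frequencies, recycled to `n_loci`) or
#' `prevalence` (a target population rate of the atypical phenotype, from
#' which a common per-locus frequency is solved with [solve_equal_c()]) must
#' be supplied; the default is `prevalence = 0.1`, the conventional Western
#' rate of left-handedness, which at one locus gives `c = 0.2`.
#'
#' @param n_loci Number of loci (`>= 1`); defaults to `length(c)` when `c`
#'   is supplied and 1 otherwise. Loci are autosomal, unlinked, and in
#'   Hardy-Weinberg proportions under random mating.
#' @param c Chance-allele frequency per locus; a scalar is recycled.
#' @param prevalence Target population rate of the atypical phenotype, used
#'   to solve for an equal per-locus `c` when `c` is missing.
#' @param penetrance A [penetrance()] triple.
#' @return A `dc_model` object.
#' @examples
#' dc_model()                      # single locus, c = 0.2, 10% left-handed
#' dc_model(n_loci = 10, prevalence = 0.1)
#' dc_model(c = c(0.05, 0.1))      # two loci, unequal frequencies
#' @export
dc_model <- function(n_loci = NULL, c = NULL, prevalence = NULL,
                     penetrance = dcmodel::penetrance()) {
  if (is.null(n_loci)) n_loci <- if (is.null(c)) 1L else length(c)
  n_loci <- check_count(n_loci, "n_loci")
  pen <- as_penetrance(penetrance)
  if (!is.null(c) && !is.null(prevalence)) {
    stop_invalid("Supply `c` or `prevalence`, not both.")
  }
  if (is.null(c)) {
    if (is.null(prevalence)) prevalence <- 0.1
    check_probability(prevalence, "prevalence", 1)
    c <- solve_equal_c(n_loci, prevalence, pen)$c
  }
  check_probability(c, "c")
  if (length(c) == 1) c <- rep(c, n_loci)
  if (length(c) != n_loci) {
    stop_invalid("`c` must have length 1 or `n_loci`.")
  }
  structure(
    list(n_loci = n_loci, c = as.numeric(c), penetrance = pen),
    class = "dc_model"
  )
}

is_dc_model <- function(x) inherits(x, "dc_model")

check_model <- function(model) {
  if (!is_dc_model(model)) stop_invalid("`model` must be a `dc_model` object.")
  invisible(model)
}

#' @export
print.dc_model <- function(x, ...) {
  cat(sprintf("<dc_model>  %d %s\n", x$n_loci,
              if (x$n_loci == 1) "locus" else "unlinked loci"))
  if (length(unique(x$c)) == 1) {
    cat(sprintf("  chance-allele frequency c = %.5f%s\n", x$c[[1]],
                if (x$n_loci > 1) " (all loci)" else ""))
  } else {
    cat("  chance-allele frequencies: ",
        paste(sprintf("%.5f", x$c), collapse = " "), "\n", sep = "")
  }
  cat(sprintf("  penetrance (DD, DC, CC): %s\n",
              paste(format(as.numeric(x$penetrance)), collapse = ", ")))
  cat(sprintf("  implied prevalence P(L) = %.5f\n", population_left_rate(x)))
  invisible(x)
}

#' @rdname dc_model
#' @param x A `dc_model`.
#' @param ... Unused.
#' @return `tidy()` returns one row per locus with its chance-allele
#'   frequency and Hardy-Weinberg genotype probabilities; `glance()` a
#'   one-row summary with the implied population prevalence.
#' @export
tidy.dc_model <- function(x, ...) {
  tibble::tibble(
    locus = seq_len(x$n_loci),
    c = x$c,
    p_dd = (1 - x$c)^2,
    p_dc = 2 * x$c * (1 - x$c),
    p_cc = x$c^2
  )
}

#' @rdname dc_model
#' @export
glance.dc_model <- function(x, ...) {
  tibble::tibble(
    n_loci = x$n_loci,
    c_min = min(x$c),
    c_max = max(x$c),
    p_dd = as.numeric(x$penetrance[[1]]),
    p_dc = as.numeric(x$penetrance[[2]]),
    p_cc = as.numeric(x$penetrance[[3]]),
    prevalence = population_left_rate(x)
  )
}

#' Hardy-Weinberg genotype distribution at one locus
#'
#' @param c Chance-allele frequency, in `[0, 1]`.
#' @return A tibble with columns `genotype` (`DD`, `DC`, `CC`) and `prob`
#'   (`(1-c)^2`, `2c(1-c)`, `c^2`).
#' @examples
#' hwe_genotypes(0.2)
#' @export
hwe_genotypes <- function(c) {
  check_probability(c, "c", 1)
  tibble::tibble(
    genotype = GENOTYPE_LABELS,
    prob = c((1 - c)^2, 2 * c * (1 - c), c^2)
  )
}

#' Population rate of the atypical phenotype
#'
#' The closed-form prevalence of left-handedness under a DC model. For a
#' model with penetrances \eqn{(p_{DD}, p_{DC}, p_{CC})} and chance-allele
#' frequencies \eqn{c_i},
#' \deqn{P(L) = p_{CC}\,[1 - \prod_i(1-c_i^2)] +
#'       p_{DC}\,[\prod_i(1-c_i^2) - \prod_i(1-c_i)^2] +
#'       p_{DD}\,\prod_i(1-c_i)^2,}
#' the three bracketed terms being the probabilities of carrying at least one
#' `CC` locus, at least one heterozygous locus but no `CC`, and only `D`
#' alleles. With one locus and the default penetrances this reduces to `c/2`.
#'
#' @param model A [dc_model()].
#' @return A single probability.
#' @examples
#' population_left_rate(dc_model(c = 0.2))  # 0.10
#' @export
population_left_rate <- function(model) {
  check_model(model)
  left_rate_closed_form(model$c, model$penetrance)
}

#' @rdname population_left_rate
#' @param c_values Per-locus chance-allele frequencies.
#' @param penetrance A [penetrance()] triple.
#' @export
left_rate_closed_form <- function(c_values, penetrance = dcmodel::penetrance()) {
  check_probability(c_values, "c_values")
  if (length(c_values) < 1) stop_invalid("`c_values` must be non-empty.")
  pen <- as_penetrance(penetrance)
  no_cc <- prod(1 - c_values^2)     # no locus is CC
  all_dd <- prod((1 - c_values)^2)  # every locus is DD
  pen[[3]] * (1 - no_cc) + pen[[2]] * (no_cc - all_dd) + pen[[1]] * all_dd
}

#' Solve the prevalence equation for an equal per-locus allele frequency
#'
#' Finds the common chance-allele frequency `c` at which an `n`-locus DC
#' model attains a target population prevalence, by bracketed root search of
#' the closed-form prevalence equation on `[0, 1]` (the prevalence is
#' monotone in `c` whenever the penetrances are ordered, so the root is
#' unique). The root is located to an absolute tolerance of 1e-12.
#'
#' @param n_loci Number of loci.
#' @param target_prevalence Desired population rate of the atypical
#'   phenotype. Must lie between the rates attainable at `c = 0` and `c = 1`.
#' @param penetrance A [penetrance()] triple.
#' @return A one-row tibble with columns `n_loci`, `target_prevalence` and
#'   `c` (the solved frequency, unrounded).
#' @examples
#' solve_equal_c(1, 0.10)   # c = 0.2
#' solve_equal_c(10, 0.10)  # c = 0.02473
#' @export
solve_equal_c <- function(n_loci, target_prevalence,
                          penetrance = dcmodel::penetrance()) {
  n_loci <- check_count(n_loci, "n_loci")
  check_probability(target_prevalence, "target_prevalence", 1)
  pen <- as_penetrance(penetrance)
  f <- function(c) left_rate_closed_form(rep(c, n_loci), pen) - target_prevalence
  lo <- f(0)
  hi <- f(1)
  if (lo == 0) {
    root <- 0
  } else if (hi == 0) {
    root <- 1
  } else if (sign(lo) == sign(hi)) {
    stop_no_solution(sprintf(
      "Prevalence %g is not attainable for n_loci = %d (range [%g, %g]).",
      target_prevalence, n_loci, min(lo, hi) + target_prevalence,
      max(lo, hi) + target_prevalence
    ))
  } else {
    root <- stats::uniroot(f, c(0, 1), tol = 1e-12)$root
  }
  tibble::tibble(
    n_loci = n_loci,
    target_prevalence = target_prevalence,
    c = root
  )
}
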