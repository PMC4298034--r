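#' Damage-rule penetrance of a multilocus genotype
#'
#' The multilocus DC model uses a damage rule akin to locus heterogeneity in
#' primary ciliary dyskinesia: being homozygous for the chance allele at
#' *any* locus places an individual in the highest penetrance class
#' (additional `CC` loci have no further effect), otherwise heterozygosity
#' at any locus places it in the middle class, otherwise the baseline class.
#' Equivalently, the effective class is the maximum per-locus genotype class.
#'
#' @param genotype Per-locus genotypes for one individual: an integer vector
#'   of chance-allele counts (0, 1, 2) or a character vector of `"DD"`,
#'   `"DC"`, `"CC"` labels. A matrix (individuals in rows) is also accepted.
#' @param penetrance A [penetrance()] triple.
#' @return The probability of the atypical phenotype (a vector for matrix
#'   input).
#' @examples
#' damage_rule_penetrance(c(0, 0, 0, 0))        # all DD: 0
#' damage_rule_penetrance(c(2, 1, 1, 1))        # a CC locus dominates: 0.5
#' damage_rule_penetrance(c("DC", "DD", "DD"))  # one heterozygous locus: 0.25
#' @export
damage_rule_penetrance <- function(genotype, penetrance = dcmodel::penetrance()) {
  pen <- as.numeric(as_penetrance(penetrance))
  if (is.character(genotype)) {
    m <- match(genotype, GENOTYPE_LABELS)
    if (anyNA(m)) stop_invalid("Genotype labels must be 'DD', 'DC' or 'CC'.")
    genotype <- array(m - 1L, dim = dim(genotype) %||% length(genotype))
  }
  if (length(genotype) == 0) stop_invalid("`genotype` must be non-empty.")
  if (!is.numeric(genotype) || anyNA(genotype) || any(!genotype %in% 0:2)) {
    stop_invalid("`genotype` must contain chance-allele counts 0, 1 or 2.")
  }
  cls <- if (is.matrix(genotype)) {
    apply(genotype, 1, max)
  } else {
    max(genotype)
  }
  pen[cls + 1]
}

#' Sample multilocus genotypes under Hardy-Weinberg equilibrium
#'
#' Draws each locus independently from Hardy-Weinberg proportions at its
#' chance-allele frequency.
#'
#' @param model A [dc_model()].
#' @param n Number of individuals.
#' @param seed Optional integer seed; when supplied the draw is reproducible
#'   and the caller's RNG stream is left untouched.
#' @return An integer matrix (`n` rows, `n_loci` columns) of chance-allele
#'   counts per locus.
#' @examples
#' g <- sample_genotypes(dc_model(c = 0.2), 5, seed = 1)
#' damage_rule_penetrance(g)
#' @export
sample_genotypes <- function(model, n, seed = NULL) {
  check_model(model)
  n <- check_count(n, "n")
  with_seed(seed, {
    g <- matrix(0L, n, model$n_loci)
    for (i in seq_len(model$n_loci)) {
      ci <- model$c[[i]]
      u <- stats::runif(n)
      g[, i] <- (u > (1 - ci)^2) + (u > 1 - ci^2)
    }
    colnames(g) <- paste0("locus", seq_len(model$n_loci))
    g
  })
}

#' Mendelian segregation of multilocus genotypes
#'
#' Produces one gamete per parental genotype: at each locus one of the
#' parent's two alleles is chosen uniformly, and loci segregate
#' independently (unlinked).
#'
#' @param genotypes An integer matrix of chance-allele counts, as returned
#'   by [sample_genotypes()] (a single genotype vector is also accepted).
#' @param seed Optional integer seed.
#' @return An integer matrix of transmitted chance-allele indicators (0 or 1
#'   per locus). Summing two gametes gives the offspring genotype.
#' @examples
#' p1 <- sample_genotypes(dc_model(c = 0.2), 3, seed = 1)
#' p2 <- sample_genotypes(dc_model(c = 0.2), 3, seed = 2)
#' offspring <- meiosis(p1, seed = 3) + meiosis(p2, seed = 4)
#' @export
meiosis <- function(genotypes, seed = NULL) {
  if (is.vector(genotypes)) genotypes <- matrix(genotypes, nrow = 1)
  if (!is.numeric(genotypes) || anyNA(genotypes) || any(!genotypes %in% 0:2)) {
    stop_invalid("`genotypes` must contain chance-allele counts 0, 1 or 2.")
  }
  with_seed(seed, {
    # P(transmit C) = 0, 1/2, 1 for counts 0, 1, 2
    gam <- matrix(
      as.integer(stats::runif(length(genotypes)) < genotypes / 2),
      nrow = nrow(genotypes)
    )
    colnames(gam) <- colnames(genotypes)
    gam
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
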