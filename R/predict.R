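# Exact (enumeration-based) predictions under a DC model.
#
# Loci are unlinked and iid given their frequencies, and the damage rule
# maps a multilocus genotype to the *maximum* per-locus genotype class
# (0 = DD, 1 = DC, 2 = CC).  For any set of relatives whose per-locus
# genotypes are jointly independent across loci, the joint distribution of
# their genotype *classes* therefore follows from products of per-locus
# lattice CDFs:
#     P(class_1 <= a, ..., class_k <= d) = prod_i P_i(g_1 <= a, ..., g_k <= d)
# and finite differencing on the {0,1,2}^k lattice recovers the joint pmf.
# With n_loci = 1 this reduces to plain genotype enumeration, so the
# single-locus model is the n = 1 special case of the same code path.

# per-locus transmission probability of the chance allele by genotype class
TRANSMIT_C <- c(0, 0.5, 1)

locus_genotype_probs <- function(ci) {
  c((1 - ci)^2, 2 * ci * (1 - ci), ci^2)
}

# per-locus joint pmf over (parent1, parent2, offspring) genotype classes
locus_trio_pmf <- function(ci) {
  g <- locus_genotype_probs(ci)
  arr <- array(0, c(3, 3, 3))
  for (i in 1:3) {
    for (j in 1:3) {
      t1 <- TRANSMIT_C[i]
      t2 <- TRANSMIT_C[j]
      off <- c((1 - t1) * (1 - t2), t1 * (1 - t2) + (1 - t1) * t2, t1 * t2)
      arr[i, j, ] <- g[i] * g[j] * off
    }
  }
  arr
}

# per-locus joint pmf over (parent1, parent2, offspring1, offspring2)
locus_quad_pmf <- function(ci) {
  g <- locus_genotype_probs(ci)
  arr <- array(0, c(3, 3, 3, 3))
  for (i in 1:3) {
    for (j in 1:3) {
      t1 <- TRANSMIT_C[i]
      t2 <- TRANSMIT_C[j]
      off <- c((1 - t1) * (1 - t2), t1 * (1 - t2) + (1 - t1) * t2, t1 * t2)
      arr[i, j, , ] <- g[i] * g[j] * outer(off, off)
    }
  }
  arr
}

# joint pmf of genotype classes (maxima over loci) for k related individuals,
# given a per-locus pmf generator returning a {3}^k array for frequency ci
class_joint_pmf <- function(c_values, locus_pmf) {
  k <- length(dim(locus_pmf(0.5)))
  dims <- rep(3, k)
  # cumulative products over loci of the per-locus lattice CDFs
  cdf <- array(1, dims)
  for (ci in c_values) {
    p <- locus_pmf(ci)
    f <- p
    for (d in seq_len(k)) f <- apply_cumsum(f, d)
    cdf <- cdf * f
  }
  # finite differencing: pmf(x) = sum over corners (-1)^|delta| cdf(x - delta)
  pmf <- array(0, dims)
  idx <- as.matrix(expand.grid(rep(list(1:3), k)))
  corners <- as.matrix(expand.grid(rep(list(0:1), k)))
  for (r in seq_len(nrow(idx))) {
    x <- idx[r, ]
    s <- 0
    for (cr in seq_len(nrow(corners))) {
      y <- x - corners[cr, ]
      if (all(y >= 1)) {
        s <- s + (-1)^sum(corners[cr, ]) * cdf[matrix(y, 1)]
      }
    }
    pmf[matrix(x, 1)] <- s
  }
  # clip tiny negative rounding residue
  pmf[pmf < 0 & pmf > -1e-14] <- 0
  pmf
}

apply_cumsum <- function(a, dim) {
  aperm_back <- function(x, perm) aperm(x, order(perm))
  k <- length(dim(a))
  perm <- c(dim, setdiff(seq_len(k), dim))
  b <- aperm(a, perm)
  db <- dim(b)
  b <- apply(array(b, c(db[1], prod(db[-1]))), 2, cumsum)
  aperm_back(array(b, db), perm)
}

# marginal distribution of one individual's genotype class
class_pmf <- function(c_values) {
  no_cc <- prod(1 - c_values^2)
  all_dd <- prod((1 - c_values)^2)
  c(all_dd, no_cc - all_dd, 1 - no_cc)
}

match_arg_checked <- function(arg, choices, what) {
  if (!is.character(arg) || length(arg) < 1 || !(arg[[1]] %in% choices)) {
    stop_invalid(sprintf("`%s` must be one of: %s.", what,
                         paste(choices, collapse = ", ")))
  }
  arg[[1]]
}

#' Genotype distribution conditional on handedness
#'
#' Bayes posterior over the genotype classes at one locus given an
#' individual's phenotype. With one locus this is the posterior over `DD`,
#' `DC`, `CC`; left-handers can only be `DC` or `CC` under the default
#' penetrances. For a multilocus model the posterior is the locus-marginal
#' one, computed exactly by combining the focal locus with the class
#' distribution of the remaining loci.
#'
#' @param model A [dc_model()].
#' @param hand `"R"` or `"L"`.
#' @param locus Focal locus index (multilocus models).
#' @return A tibble with columns `genotype` and `prob`.
#' @examples
#' genotype_given_hand(dc_model(c = 0.2), "L")  # (0, 0.8, 0.2)
#' @export
genotype_given_hand <- function(model, hand = c("R", "L"), locus = 1) {
  check_model(model)
  hand <- match_arg_checked(hand, c("R", "L"), "hand")
  locus <- check_count(locus, "locus")
  if (locus > model$n_loci) stop_invalid("`locus` exceeds `n_loci`.")
  pen <- as.numeric(model$penetrance)
  gi <- locus_genotype_probs(model$c[[locus]])
  other <- class_pmf(model$c[-locus])
  if (model$n_loci == 1) other <- c(1, 0, 0)
  post <- numeric(3)
  for (a in 1:3) {
    # phenotype probability given focal genotype, marginalized over the
    # damage-rule class contributed by the other loci
    p_left <- sum(other * pen[pmax(a, 1:3)])
    post[a] <- gi[a] * if (hand == "L") p_left else 1 - p_left
  }
  tot <- sum(post)
  if (tot <= 0) {
    stop_degenerate(sprintf("Phenotype '%s' has probability 0 under this model.", hand))
  }
  tibble::tibble(genotype = GENOTYPE_LABELS, prob = post / tot)
}

# joint pmf over (parent1, parent2, offspring) classes together with the
# phenotype weights for a parental phenotype stratum
parent_stratum_weights <- function(pen, parents) {
  # weight(a, b) = P(observed parental phenotypes | classes a, b); phenotypes
  # are independent given genotype (deep chance extended to parents)
  switch(parents,
    RxR = function(a, b) (1 - pen[a]) * (1 - pen[b]),
    RxL = function(a, b) (1 - pen[a]) * pen[b] + pen[a] * (1 - pen[b]),
    LxL = function(a, b) pen[a] * pen[b]
  )
}

#' Offspring handedness by parental phenotype
#'
#' Exact prediction of the rate of left-handedness among offspring of
#' right- and left-handed parental pairings, under random mating,
#' Hardy-Weinberg proportions and Mendelian segregation, with parental
#' phenotypes independent given their genotypes. `R x L` is unordered.
#' For the default single-locus model at 10% prevalence the three rates are
#' 7.78%, 18.89% and 30.00%.
#'
#' @param model A [dc_model()].
#' @param parents `"RxR"`, `"RxL"` or `"LxL"`.
#' @return `offspring_left_rate()` returns a single probability;
#'   `family_predictions()` a tibble with one row per parental pairing.
#' @examples
#' offspring_left_rate(dc_model(c = 0.2), "LxL")  # 0.30
#' family_predictions(dc_model(n_loci = 10, prevalence = 0.1))
#' @export
offspring_left_rate <- function(model, parents = c("RxR", "RxL", "LxL")) {
  check_model(model)
  parents <- match_arg_checked(parents, PARENT_LABELS, "parents")
  pen <- as.numeric(model$penetrance)
  pmf <- class_joint_pmf(model$c, locus_trio_pmf)
  w <- parent_stratum_weights(pen, parents)
  num <- 0
  den <- 0
  for (a in 1:3) {
    for (b in 1:3) {
      for (d in 1:3) {
        wt <- pmf[a, b, d] * w(a, b)
        num <- num + wt * pen[d]
        den <- den + wt
      }
    }
  }
  if (den <= 0) {
    stop_degenerate(sprintf("Parental phenotype class '%s' has probability 0.", parents))
  }
  num / den
}

#' @rdname offspring_left_rate
#' @export
family_predictions <- function(model) {
  check_model(model)
  tibble::tibble(
    parents = PARENT_LABELS,
    p_left = vapply(PARENT_LABELS, function(p) offspring_left_rate(model, p),
                    numeric(1), USE.NAMES = FALSE)
  )
}

#' Twin pair handedness distributions
#'
#' Probabilities of concordant-right (`R-R`), discordant (`R-L`, unordered)
#' and concordant-left (`L-L`) twin pairs. Monozygotic twins share their
#' genotype and draw phenotypes independently given it (deep chance); a `CC`
#' MZ pair is thus R-R/R-L/L-L with probabilities 1/4, 1/2, 1/4 and a `DC`
#' pair 9/16, 6/16, 1/16. Dizygotic twins are modeled as full siblings:
#' parents mate at random, each twin receives an independent Mendelian
#' genotype given the parents, and phenotypes are independent given
#' genotypes. For the default single-locus model at 10% prevalence the MZ
#' distribution is (83%, 14%, 3%) and the DZ discordance is 16%.
#'
#' @param model A [dc_model()].
#' @param zygosity `"MZ"` or `"DZ"`.
#' @param parents Optionally condition on the parental phenotype pairing
#'   (`"RxR"`, `"RxL"`, `"LxL"`); `NULL` for the population distribution.
#' @param genotype Optionally condition an MZ pair on its shared genotype
#'   class (`"DD"`, `"DC"`, `"CC"`, single-locus models only).
#' @return A tibble with columns `zygosity`, `pair` and `prob`.
#' @examples
#' twin_distribution(dc_model(c = 0.2), "MZ")
#' twin_distribution(dc_model(c = 0.2), "DZ")
#' twin_distribution(dc_model(c = 0.2), "MZ", parents = "LxL")
#' @export
twin_distribution <- function(model, zygosity = c("MZ", "DZ"), parents = NULL,
                              genotype = NULL) {
  check_model(model)
  zygosity <- match_arg_checked(zygosity, c("MZ", "DZ"), "zygosity")
  pen <- as.numeric(model$penetrance)
  pair_probs <- function(p1, p2) {
    c((1 - p1) * (1 - p2), (1 - p1) * p2 + p1 * (1 - p2), p1 * p2)
  }

  if (!is.null(genotype)) {
    genotype <- match_arg_checked(genotype, GENOTYPE_LABELS, "genotype")
    if (zygosity != "MZ") {
      stop_invalid("Conditioning on a shared genotype is defined for MZ twins only.")
    }
    if (!is.null(parents)) {
      stop_invalid("Condition on `parents` or `genotype`, not both.")
    }
    p <- pen[match(genotype, GENOTYPE_LABELS)]
    probs <- pair_probs(p, p)
  } else if (is.null(parents)) {
    if (zygosity == "MZ") {
      pc <- class_pmf(model$c)
      probs <- Reduce(`+`, lapply(1:3, function(g) pc[g] * pair_probs(pen[g], pen[g])))
    } else {
      pmf <- class_joint_pmf(model$c, locus_quad_pmf)
      probs <- c(0, 0, 0)
      for (k in 1:3) for (l in 1:3) {
        probs <- probs + sum(pmf[, , k, l]) * pair_probs(pen[k], pen[l])
      }
    }
  } else {
    parents <- match_arg_checked(parents, PARENT_LABELS, "parents")
    w <- parent_stratum_weights(pen, parents)
    probs <- c(0, 0, 0)
    den <- 0
    if (zygosity == "MZ") {
      pmf <- class_joint_pmf(model$c, locus_trio_pmf)
      for (a in 1:3) for (b in 1:3) for (d in 1:3) {
        wt <- pmf[a, b, d] * w(a, b)
        den <- den + wt
        probs <- probs + wt * pair_probs(pen[d], pen[d])
      }
    } else {
      pmf <- class_joint_pmf(model$c, locus_quad_pmf)
      for (a in 1:3) for (b in 1:3) for (k in 1:3) for (l in 1:3) {
        wt <- pmf[a, b, k, l] * w(a, b)
        den <- den + wt
        probs <- probs + wt * pair_probs(pen[k], pen[l])
      }
    }
    if (den <= 0) {
      stop_degenerate(sprintf("Parental phenotype class '%s' has probability 0.", parents))
    }
    probs <- probs / den
  }

  tibble::tibble(zygosity = zygosity, pair = PAIR_LABELS, prob = as.numeric(probs))
}

#' @rdname twin_distribution
#' @export
mz_twin_distribution <- function(model) twin_distribution(model, "MZ")

#' @rdname twin_distribution
#' @export
dz_twin_distribution <- function(model) twin_distribution(model, "DZ")

#' Joint distribution of handedness and language dominance
#'
#' Under pleiotropy, the same genotype classes determine both handedness and
#' hemispheric language dominance, with the two phenotypes drawn
#' independently given the genotype. By default the language penetrances
#' (probability of right-hemisphere language by class) equal the handedness
#' penetrances, so the marginal rate of right-language dominance equals the
#' rate of left-handedness. At 10% prevalence this predicts right-language
#' dominance in 7.8% of right-handers and 30% of left-handers.
#'
#' @param model A [dc_model()].
#' @param language_penetrance A [penetrance()] triple giving the probability
#'   of right-hemisphere language dominance per genotype class; defaults to
#'   the model's handedness penetrances.
#' @return A `dc_lateralization` object with elements `joint` (tibble over
#'   hand x language) and `conditional` (P(language | hand)).
#' @examples
#' lateralization_table(dc_model(c = 0.2))
#' @export
lateralization_table <- function(model, language_penetrance = NULL) {
  check_model(model)
  pen <- as.numeric(model$penetrance)
  lang <- if (is.null(language_penetrance)) pen else {
    as.numeric(as_penetrance(language_penetrance, "language_penetrance"))
  }
  pc <- class_pmf(model$c)
  cells <- expand.grid(hand = c("R", "L"), language = c("left", "right"),
                       stringsAsFactors = FALSE)
  prob <- vapply(seq_len(nrow(cells)), function(r) {
    ph <- if (cells$hand[r] == "L") pen else 1 - pen
    pl <- if (cells$language[r] == "right") lang else 1 - lang
    sum(pc * ph * pl)
  }, numeric(1))
  joint <- tibble::tibble(hand = cells$hand, language = cells$language, prob = prob)
  p_hand <- c(R = sum(prob[cells$hand == "R"]), L = sum(prob[cells$hand == "L"]))
  cond <- tibble::tibble(
    hand = c("R", "L"),
    p_rightlang_given_hand = vapply(c("R", "L"), function(h) {
      if (p_hand[[h]] <= 0) {
        stop_degenerate(sprintf("Handedness class '%s' has probability 0.", h))
      }
      prob[cells$hand == h & cells$language == "right"] / p_hand[[h]]
    }, numeric(1), USE.NAMES = FALSE)
  )
  structure(list(joint = joint, conditional = cond), class = "dc_lateralization")
}

#' @export
print.dc_lateralization <- function(x, ...) {
  cat("<dc_lateralization>  joint distribution of handedness and language\n")
  print(tidyr::pivot_wider(x$joint, names_from = "language", values_from = "prob"))
  cat("P(right-hemisphere language | handedness):\n")
  print(x$conditional)
  invisible(x)
}

#' @rdname lateralization_table
#' @param x A `dc_lateralization` object.
#' @param ... Unused.
#' @export
tidy.dc_lateralization <- function(x, ...) x$joint
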