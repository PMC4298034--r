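# Independent brute-force oracles. These deliberately take different code
# paths from the package (explicit expand.grid enumeration instead of
# lattice-CDF products) so agreement is a genuine cross-check.

# all multilocus genotypes as chance-allele-count vectors with their HWE probs
enumerate_genotypes <- function(c_values) {
  n <- length(c_values)
  g <- as.matrix(expand.grid(rep(list(0:2), n)))
  probs <- apply(g, 1, function(row) {
    prod(vapply(seq_len(n), function(i) {
      ci <- c_values[i]
      c((1 - ci)^2, 2 * ci * (1 - ci), ci^2)[row[i] + 1]
    }, numeric(1)))
  })
  list(genotypes = g, probs = probs)
}

oracle_left_rate <- function(c_values, pen = c(0, 0.25, 0.5)) {
  e <- enumerate_genotypes(c_values)
  sum(e$probs * pen[apply(e$genotypes, 1, max) + 1])
}

# offspring genotype pmf at one locus given parental allele counts
oracle_mendel <- function(g1, g2) {
  t1 <- g1 / 2
  t2 <- g2 / 2
  c((1 - t1) * (1 - t2), t1 * (1 - t2) + (1 - t1) * t2, t1 * t2)
}

# exhaustive enumeration over 3^n x 3^n parental genotype pairs; offspring
# damage-class distribution built locus by locus from Mendelian transmission
oracle_offspring_class_pmf <- function(p1, p2) {
  cdf <- c(1, 1, 1) # P(offspring class <= k) running product over loci
  for (i in seq_along(p1)) {
    off <- oracle_mendel(p1[i], p2[i])
    cdf <- cdf * cumsum(off)
  }
  c(cdf[1], cdf[2] - cdf[1], cdf[3] - cdf[2])
}

oracle_family_table <- function(c_values, pen = c(0, 0.25, 0.5)) {
  e <- enumerate_genotypes(c_values)
  m <- nrow(e$genotypes)
  num <- den <- c(RxR = 0, RxL = 0, LxL = 0)
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      w <- e$probs[i] * e$probs[j]
      pL1 <- pen[max(e$genotypes[i, ]) + 1]
      pL2 <- pen[max(e$genotypes[j, ]) + 1]
      off <- oracle_offspring_class_pmf(e$genotypes[i, ], e$genotypes[j, ])
      eL <- sum(off * pen)
      wts <- c(
        RxR = (1 - pL1) * (1 - pL2),
        RxL = (1 - pL1) * pL2 + pL1 * (1 - pL2),
        LxL = pL1 * pL2
      )
      num <- num + w * wts * eL
      den <- den + w * wts
    }
  }
  num / den
}

oracle_mz_table <- function(c_values, pen = c(0, 0.25, 0.5)) {
  e <- enumerate_genotypes(c_values)
  p <- pen[apply(e$genotypes, 1, max) + 1]
  c(
    sum(e$probs * (1 - p)^2),
    sum(e$probs * 2 * p * (1 - p)),
    sum(e$probs * p^2)
  )
}

# DZ twins: six unordered single-locus mating types x 3x3 sibling genotypes
# x 2x2 phenotypes (single-locus only, as an explicitly different structure
# from the implementation's joint-lattice computation)
oracle_dz_single_locus <- function(c, pen = c(0, 0.25, 0.5)) {
  g <- c((1 - c)^2, 2 * c * (1 - c), c^2)
  matings <- rbind(
    c(1, 1), c(1, 2), c(1, 3), c(2, 2), c(2, 3), c(3, 3)
  )
  out <- c("R-R" = 0, "R-L" = 0, "L-L" = 0)
  for (r in seq_len(nrow(matings))) {
    i <- matings[r, 1]
    j <- matings[r, 2]
    w <- g[i] * g[j] * if (i == j) 1 else 2
    off <- oracle_mendel(i - 1, j - 1)
    for (k in 1:3) {
      for (l in 1:3) {
        wk <- w * off[k] * off[l]
        for (ph1 in 0:1) {
          for (ph2 in 0:1) {
            p <- wk *
              (if (ph1 == 1) pen[k] else 1 - pen[k]) *
              (if (ph2 == 1) pen[l] else 1 - pen[l])
            idx <- ph1 + ph2 + 1
            out[idx] <- out[idx] + p
          }
        }
      }
    }
  }
  out
}

# normal-approximation power for the two-proportion (allelic) comparison
oracle_power_normal <- function(f1, f2, n_alleles_1, n_alleles_2, alpha) {
  delta <- abs(f1 - f2)
  pbar <- (n_alleles_1 * f1 + n_alleles_2 * f2) / (n_alleles_1 + n_alleles_2)
  se0 <- sqrt(pbar * (1 - pbar) * (1 / n_alleles_1 + 1 / n_alleles_2))
  se1 <- sqrt(f1 * (1 - f1) / n_alleles_1 + f2 * (1 - f2) / n_alleles_2)
  z <- stats::qnorm(1 - alpha / 2)
  stats::pnorm((delta - z * se0) / se1) + stats::pnorm((-delta - z * se0) / se1)
}

# published multilocus prediction table (percent scale) used by the
# acceptance checks: columns RxR, RxL, LxL, R-R, R-L, L-L
printed_table2 <- function() {
  rows <- rbind(
    c(1,    0.20000, 7.82, 18.90, 30.63, 83.00, 14.00, 3.00),
    c(2,    0.11110, 8.15, 17.74, 25.56, 82.80, 14.40, 2.83),
    c(3,    0.07715, 8.19, 17.24, 24.17, 82.74, 14.55, 2.71),
    c(4,    0.05916, 8.29, 17.01, 22.88, 82.70, 14.64, 2.66),
    c(5,    0.04780, 8.35, 16.79, 22.60, 82.65, 14.69, 2.66),
    c(10,   0.02473, 8.38, 16.45, 21.86, 82.60, 14.85, 2.55),
    c(20,   0.01256, 8.46, 16.50, 21.53, 82.50, 14.95, 2.55),
    c(50,   0.00507, 8.52, 16.09, 20.02, 82.51, 14.97, 2.53),
    c(100,  0.00254, 8.48, 16.10, 20.28, 82.52, 14.98, 2.49),
    c(200,  0.00127, 8.55, 16.30, 20.83, 82.39, 15.09, 2.51),
    c(500,  0.00051, 8.56, 16.12, 21.06, 82.54, 14.91, 2.55),
    c(1000, 0.00026, 8.52, 16.26, 20.29, 82.46, 15.03, 2.51)
  )
  colnames(rows) <- c("n_loci", "c", "RxR", "RxL", "LxL", "R-R", "R-L", "L-L")
  as.data.frame(rows)
}

# quoted approximate 95% CI half-widths, percent scale, same column order
printed_table2_ci <- function() {
  c("RxR" = 0.05, "RxL" = 0.07, "LxL" = 0.08,
    "R-R" = 0.08, "R-L" = 0.07, "L-L" = 0.03)
}

random_penetrance <- function() {
  sort(stats::runif(3))
}
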