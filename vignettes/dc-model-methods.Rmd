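---
title: "The dextral-chance model: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The dextral-chance model: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcmodel)
```

## The model

The dextral-chance (DC) model describes handedness with a biallelic
autosomal locus: a *Dextral* allele `D` and a *Chance* allele `C`, with
penetrances for left-handedness of 0, 0.25 and 0.5 for `DD`, `DC` and `CC`.
The defining assumption is *deep chance*: the 25% and 50% rates are not
residual genetic or environmental variance but irreducible developmental
randomness, so any two phenotypes that share a genotype — the two members
of an MZ pair, handedness and language dominance in one person, a parent's
and a child's handedness given their genotypes — are conditionally
independent. Every prediction in this package follows mechanically from
that assumption plus random mating, Hardy-Weinberg proportions and
Mendelian segregation. There is no sex effect, no assortative mating, no
maternal or chorionicity effect, and the `R x L` parental pairing is
unordered; these are the assumptions under which the classical predicted
values (7.78% / 18.89% / 30.00% offspring left-handedness, the 83/14/3 MZ
distribution, 16% DZ discordance) are exact, and we adopt them as the only
mating model.

The multilocus variant has `n` unlinked loci, each with its own
chance-allele frequency $c_i$, combined by a **damage rule**: an individual
homozygous `C_iC_i` at *any* locus is in the 50% class; otherwise
heterozygous at any locus, the 25% class; otherwise fully right-handed.
The rule is motivated by molecular-machine pathologies such as primary
ciliary dyskinesia, where breaking any one of many components produces the
same phenotype and additional damage adds nothing. We implement the
precedence explicitly (`CC` anywhere beats `DC` anywhere beats baseline);
equivalently the effective class is the per-locus maximum, which is the
representation the code uses throughout. The population prevalence has the
closed form

$$P(L) = \tfrac12\Big[1 - \prod_i(1-c_i^2)\Big] +
         \tfrac14\Big[\prod_i(1-c_i^2) - \prod_i(1-c_i)^2\Big],$$

implemented in product form over possibly unequal $c_i$ (the equal-$c$
exponent form is the special case), so relaxing the equal-frequency
assumption needs no separate code path. General penetrance triples replace
the coefficients 1/2, 1/4 and 0.

## Exact predictions by lattice enumeration

Because loci are independent and the damage rule is a maximum, the joint
distribution of the genotype *classes* of any set of relatives factorizes
over loci on the $\{DD, DC, CC\}^k$ lattice:
$$P(\text{class}_1 \le a, \dots, \text{class}_k \le d)
  = \prod_i P_i(g_1 \le a, \dots, g_k \le d),$$
with the per-locus joint (parents, offspring) given by Hardy-Weinberg
weights and Mendelian transmission. Finite differencing of this CDF
recovers the exact joint class distribution for parent-parent-offspring
trios (family predictions, MZ twins conditioned on parents) and
parent-parent-offspring-offspring quadruples (DZ twins), for any number of
loci and unequal frequencies, at cost independent of $n$ beyond the
per-locus products. Single-locus results are the $n = 1$ special case of
the same code; the test suite additionally checks the lattice results
against independent brute-force `expand.grid` enumerations over all $3^n$
(and $3^n \times 3^n$ parental-pair) genotypes for small $n$, and the DZ
distribution against a six-mating-type enumeration.

Conditioning is always by exact division: family predictions condition on
the realized parental phenotype pair, with parental phenotypes independent
given their genotypes (deep chance extended to the parents; this is
required to reproduce the classical parenthetical values). Conditioning on
an impossible class — left-handed parents when no chance alleles exist —
raises a classed `degenerate-condition` error rather than returning `NaN`.

## The prevalence-equation solver

`solve_equal_c()` inverts the closed form by bracketed root search
(`stats::uniroot`) on $c \in [0,1]$ to absolute tolerance $10^{-12}$;
prevalence is monotone in $c$ for ordered penetrances, so the root is
unique, and results are conventionally displayed to 5 decimals. Solving at
10% prevalence gives 0.20000 at one locus, 0.11104 at two, 0.02473 at ten
and 0.00026 at a thousand. We note for users comparing against the
published table of these frequencies that a few of its printed entries
(n = 2, 3, 5, 100) do not satisfy the prevalence equation to their own
printed precision — substituting them back gives prevalences up to 0.0003
away from 0.10 — so this package reports the mathematical roots, which
differ from those entries in the fourth or fifth decimal.

## The pedigree simulator

`simulate_families()` and `simulate_twins()` re-derive the same quantities
by forward simulation: per replicate, two Hardy-Weinberg parents, damage-
rule phenotypes, one offspring (two for DZ pairs) by independent per-locus
Mendelian segregation, and phenotypes drawn from the offspring penetrance.
Implementation-wise the simulator iterates over loci rather than over
families, carrying a running class maximum per individual; this is exactly
the composition of `sample_genotypes()` and `meiosis()` but costs
O(replicates) memory and makes $10^6$ replicates of a 1000-locus model
practical in pure R (roughly 0.2 s per locus per million families on one
core).

Design choices, made once:

* **Stratification, not rejection.** Families are simulated
  unconditionally and stratified by the realized parental phenotype pair,
  so stratum sizes vary as in a real cohort and the confidence interval of
  each stratum reflects its own size. At 10% prevalence roughly 81% of
  $10^6$ families are R×R but only ~1% are L×L, so the L×L estimate is an
  order of magnitude noisier than the R×R one — its true 95% CI at $10^6$
  total replicates is about ±0.8 percentage points, not the ±0.08 that a
  full-sample binomial formula would suggest. Empty strata are reported as
  undefined (`NA`, flagged) rather than 0%.
* **One offspring per family**; the reported quantity is an offspring
  proportion, not a sibship structure.
* **CI formula**: the normal approximation $1.96\sqrt{p(1-p)/m}$ with the
  stratum's own $m$, no continuity correction.
* **Seeding**: one named seed per run, applied locally (the caller's RNG
  stream is untouched) and recorded in the result's attributes; identical
  seeds give bit-identical outputs.

`reproduce_table2()` chains the solver and both simulators across a vector
of locus counts and returns a long tibble with the analytic value beside
every Monte Carlo cell. The default test-suite runs use $2\times10^4$ to
$2\times10^5$ replicates with 5-standard-error tolerances computed at the
size actually used; the acceptance checks run the full 12-row table at
$10^6$ replicates.

## What the simulator does and does not emulate

The generator reproduces the model's own study conditions: random-mating
nuclear families and twin pairs at a target prevalence of 10%, with all
randomness Mendelian or deep-chance. It does not emulate real-data
features such as sex differences in prevalence, assortative mating,
measurement error in handedness classification, twin-specific biology
(chorionicity, mirror imaging), or population stratification. Passing
tests therefore demonstrate internal correctness of the model's
mathematics and simulation, not that the model fits any particular
dataset; the `compare_observed()` table is the user-facing bridge to the
classic meta-analytic observations, and shows, for example, that the model
underpredicts MZ discordance (14% vs the observed 19.3%).

## GWAS power and sample size

`case_control_allele_freqs()` inverts the penetrance model by Bayes' rule
to exact chance-allele frequencies among cases (left-handers) and controls
(0.600 and 0.156 for the single-locus model at 10% prevalence), again via
the locus-marginal-plus-remaining-class decomposition, exact for any $n$.
`gwas_power_mc()` draws case and control allele counts from binomials at
those frequencies — alleles treated as independent draws, the standard
allelic-test idealization — and scores each locus with the 1-df allelic
chi-square without continuity correction, the default association test in
case-control GWAS; no specific test is mandated by the model itself, so
this is a package choice, cross-checked in tests against
`chisq.test(correct = FALSE)` and a normal-approximation analytic power
formula. The default threshold is the conventional genome-wide
$5\times10^{-8}$ (0.05 Bonferroni-corrected for $10^6$ tests).

Perfect tagging (`tagging_r2 = 1`) is the default: the simulated marker
*is* the causal locus. Published power figures computed against a specific
genotyping chip's SNP map and the genome's LD structure are necessarily
lower; the idealized power reported here upper-bounds them, and the
acceptance checks assert the bound (e.g. per-locus power at a 375-case /
3375-control design is ≥ 99.47%, and any-locus power for a 30-locus model
at a 2350 / 21,093 design is ≥ 99.26% — both are ≈ 100% under perfect
tagging). Setting `tagging_r2 < 1` attenuates the case-control frequency
difference by $\sqrt{r^2}$ toward the pooled frequency. Because it is
ambiguous whether "power to detect an $n$-locus model" means any-locus or
per-locus detection, both are always reported; `any_locus_power` treats
loci as independent, so it is never below the per-locus maximum and equals
it at $n = 1$.

`sample_size_two_proportions()` is the pooled-variance normal
approximation without continuity correction, rounded to the nearest
integer — the unique convention that reproduces both published pair counts
(24,034 and 18,359) exactly.

## Numerical notes and limitations

* All exact computations are floating-point enumerations; distributions
  are normalized to within $10^{-12}$ and tiny negative finite-differencing
  residues (magnitude $< 10^{-14}$) are clipped to zero.
* The prevalence solver refuses unattainable targets (above the $c = 1$
  prevalence, 0.5 for the default penetrances) with a classed
  `no-solution` error.
* Monte Carlo power at very small expected counts (a handful of cases)
  leans on the chi-square approximation in the tail; for such designs an
  exact test would differ.
* The package does not implement continuous-shift (right-shift-style)
  models, sex-linked inheritance, imprinting, selection dynamics, or
  per-locus dominance variation; the damage rule is the only epistasis
  scheme.
* CLI outputs render percentages to 2 decimals and allele frequencies to
  5 decimals for display, but files written with `--out` carry full
  precision so that they round-trip to the in-process values.
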