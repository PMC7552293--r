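---
title: "Pooled genotyping of a low-frequency deletion: design, simulation, and downstream analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pooled genotyping of a low-frequency deletion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sheeppool)
```

## The problem

Genotyping a rare biallelic indel in a livestock cohort of thousands by
one-by-one PCR is wasteful: almost every reaction returns the wild-type
homozygote. Two-stage pooled screening (classic Dorfman group testing,
known in the livestock-genotyping literature as the *mathematical
expectation* method) cuts the reaction count by a factor of roughly
$2\sqrt{p}$ at minor-allele frequency $p$: DNA from $a$ animals is mixed
and amplified once; a pool in which all members share one genotype resolves
all of them at once, while a pool showing more than one genotype is
re-examined member by member.

`sheeppool` implements that workflow end to end for a deletion segregating
at $p \approx 0.01$ in a multi-breed sheep cohort: the analytic design
surface, a simulator of the screen, per-breed diversity statistics,
EM-based linkage-disequilibrium (LD) estimation against partner loci, and a
nonparametric genotype–trait association stage. A synthetic-data module
generates cohorts with the statistical structure the analysis assumes, so
the whole chain is testable without animal data.

## The design model

With $N$ samples, pool size $a$, and positive-sample frequency $p$, the
expected number of reactions is

$$
n(a) \;=\; N\left(\tfrac{1}{a}(1-p)^a
  + \left(1+\tfrac{1}{a}\right)\bigl(1-(1-p)^a\bigr)\right)
  \;=\; N\left(\tfrac{1}{a} + 1 - (1-p)^a\right),
$$

one reaction per pool plus a full-pool retest of every non-uniform pool.
The two forms are algebraically identical; the first is how the expectation
is usually written in the pooled-genotyping literature, the second is the
Dorfman form. The continuous minimizer sits near $a^* \approx 1/\sqrt{p}$;
`design_curve()` evaluates the integer range (default 3–20) and flags the
argmin, breaking ties toward the smaller pool because smaller pools put
fewer samples at risk per retest batch. At $N = 2350$, $p = 0.01$ the
integer optimum is $a = 11$ with $459.6$ expected reactions — 19.6 % of the
one-by-one cost.

Two deliberate modelling conventions:

* **Plug-in $p$.** Field practice plugs the estimated *minor-allele*
  frequency straight into the formula, although under Hardy–Weinberg the
  probability that an individual triggers pool heterogeneity is the carrier
  frequency $2p(1-p) \approx 2p$. The analytic module follows the plug-in
  convention exactly; the simulator exposes both readings, and
  `analysis/02_screen_simulation.R` prints the gap rather than hiding it.
* **Continuous expectation.** The formula ignores the remainder pool
  ($2350 = 213 \times 11 + 7$); the simulator handles the remainder
  explicitly as its own smaller pool.

`estimate_pilot_maf()` supplies $p$ from a pilot of individually genotyped
animals (the convention is 50); the estimate is the minor-allele count over
twice the pilot size, folded to $\le 0.5$.

## The simulator

`make_pools()` partitions a seeded random permutation of the cohort into
consecutive pools; `screen_pools()` charges one reaction per pool and
retests every member of each *mixed* pool. Positivity is "the pool shows
more than one genotype", not "the pool contains a carrier": a uniform
all-heterozygote pool would not trigger retests. At frequencies near 0.01
the two definitions coincide to order $p^a$, but the distinction is kept
because it is what the assay actually observes. The assay is error-free by
default (heteroduplex detection of heterozygotes in a pool is treated as
perfectly sensitive); a per-pool false-negative rate is available as an
explicit flag, in which case a missed pool's members are called at the
pool's majority genotype. Calls are therefore guaranteed to round-trip to
the true genotypes whenever `fn_rate = 0`, and the tests assert that
identity.

## Per-breed locus statistics

`locus_stats()`/`breed_table()` compute genotype and allele frequencies,
the minor-allele frequency, and the diversity panel in its
allele-frequency (expected, Nei) form: homozygosity $Ho = p^2 + q^2$,
heterozygosity $He = 1 - Ho$, effective allele number $Ne = 1/Ho$. At the
frequencies of interest the observed-genotype-share versions round
identically at the 3-decimal precision such tables are published with, and
the expected form keeps the identities $Ho + He = 1$ and $Ne \cdot Ho = 1$
exact. Table output rounds half-up to 3 decimals; full precision is kept
internally. Monomorphic breeds are legal inputs ($He = 0$, $Ne = 1$). A
Hardy–Weinberg exact test (`hwe_exact_test()`) is offered as a diagnostic
but is not part of the published table surface.

## Linkage disequilibrium

`em_haplotypes()` estimates the four haplotype frequencies of a locus pair
from unphased genotypes. Only the double heterozygote is phase-ambiguous;
the E-step splits it between coupling (AB/ab) and repulsion (Ab/aB) in
proportion to their current probabilities, and the M-step re-normalizes
haplotype counts. Numerical choices: initialization at linkage equilibrium
($p_{AB} = p_A p_B$), tolerance $10^{-8}$ on the log-likelihood increment,
cap of 1000 iterations with an explicit non-convergence flag, and EM's
margin-preservation property (estimated allele frequencies equal observed
ones) asserted in the tests to $10^{-9}$.

From the converged $p_{AB}$: $D = p_{AB} - p_A p_B$; $D' = |D|/D_{\max}$
with the standard Lewontin bound ($D_{\max} = \min(p_A(1-p_B),\,(1-p_A)p_B)$
for $D>0$, $\min(p_A p_B,\,(1-p_A)(1-p_B))$ for $D<0$); and
$r^2 = D^2/(p_A(1-p_A)p_B(1-p_B))$. $D'$ is reported as a magnitude.
Classification: *complete* iff $D' = 1$ and $r^2 = 1$ (within $10^{-9}$);
*strong* iff $r^2 > 0.33$; *weak* otherwise. The conventional inequalities
are strict and leave $r^2 = 0.33$ open; it is assigned to *weak*.

A rare focal allele caps attainable $r^2$ at roughly
$p_{\text{focal}}/p_{\text{partner}}$, so for a deletion at $p = 0.007$
against partners at 0.05–0.08 the weak-LD verdict is nearly forced — which
is exactly the scientific point of running the analysis at realistic
frequencies, and what `analysis/04_ld_analysis.R` reproduces on synthetic
genotypes at $n = 276$.

## Genotype–trait association

Growth traits in sheep typically fail normality, so the association stage
is nonparametric throughout:

* `ks_normality()` computes the one-sample Kolmogorov–Smirnov statistic
  against a normal with sample-estimated mean and SD, with the asymptotic
  Kolmogorov p-value as default (the common statistics-package behaviour
  when parameters are estimated in place). Because estimating parameters
  makes that p-value conservative, a seeded Monte-Carlo Lilliefors p-value
  is available behind an explicit flag; neither variant is privileged.
* `mann_whitney()` computes $U$ from midranks. Exact mode evaluates the
  full null permutation distribution via the standard count recursion
  $c(u; m, n) = c(u-n;\, m-1, n) + c(u;\, m, n-1)$ — identical to
  enumerating all $\binom{m+n}{m}$ rank assignments, which the tests verify
  by brute force for all shapes with $m+n \le 10$. Exact mode is
  auto-selected when the smaller arm has at most 10 observations and the
  pooled data are tie-free (carrier arms of 9 and 4, as arise at these
  allele frequencies, are inside that range); otherwise the tie-corrected
  normal approximation with continuity correction is used. The two agree
  within 0.02 by $n_1 = n_2 = 20$.
* `association_table()` reports one row per (sex, trait) with arithmetic
  mean ± standard error per arm — the least-squares means of a
  covariate-free comparison reduce to exactly that — plus $U$, the
  two-sided p-value and a significance flag at $\alpha = 0.05$. No
  multiple-testing correction is applied by default, matching how such
  trait panels are conventionally reported; `p.adjust` can be applied to
  the returned column by users who want one.

## The synthetic-data module

The generators define the study conditions; they are first-class, tested
code:

* **Population.** Genotypes are drawn per breed under Hardy–Weinberg at
  breed-specific deletion-allele frequencies; defaults mirror a seven-breed
  cohort of 2350 with frequencies 0.007–0.011 in four breeds and 0 in
  three. Sexes are Bernoulli(0.5) unless per-breed counts are given (the
  focal breed uses 458 rams / 449 ewes).
* **Traits.** One row per animal; value = location + effect × carrier +
  scale × noise. The carrier effect is dominant (heterozygotes shifted) —
  at these frequencies deletion homozygotes essentially never occur, and
  none were observed. Noise families are fixed as: *skewed* = standardized
  shifted log-normal ($\sigma_{\log} = 0.8$, skewness ≈ 3) — the default,
  because growth data in such cohorts are reported as non-normal without a
  stated distribution; *heavy-tailed* = $t_3/\sqrt{3}$; *normal* =
  Gaussian. Default locations are adult body-measurement means and default
  scales are per-animal SDs consistent with standard errors of 0.03–0.21
  at arm sizes near 450 (e.g. body length: mean 64.85 cm, SD 4.45 cm).
* **Two-locus genotypes.** Haplotype frequencies are constructed as
  $p_{AB} = p_A p_B + D' \cdot D_{\max}$ (positive coupling), individuals
  as two independent haplotype draws; the LD module recovers the generator
  $D'$ within 0.05 at $n = 10^4$, which is the module's round-trip test.

What the generator does **not** emulate: pedigree or relatedness structure,
breed-by-trait baseline differences, genotyping error, shared environment,
or multi-allelic loci. Passing tests therefore demonstrate that the
*procedures* are correct and calibrated under idealized sampling — they do
not certify behaviour on real cohorts with cryptic relatedness, where
rank-test type-I error can drift from nominal.

## Determinism and problem sizes

Every stochastic function takes an integer seed and restores the caller's
RNG state; child streams are derived, not reused, so stages cannot alias.
`run_pipeline()` writes logs without timestamps, making same-seed runs
byte-identical — an invariant the tests assert file by file. The pilot
stage floors the design $p$ at $1/(2 n_{\text{pilot}})$ when the pilot is
monomorphic, since such a pilot cannot distinguish $p = 0$ from anything
below its resolution and a zero $p$ degenerates the design curve.

Monte-Carlo sizes in the tests were chosen for standard-error budgets, not
speed: 2000 replicates put the simulated mean reaction count within ±2.2
(2 SE) of its expectation of ~460, comfortably inside the 1 % band being
checked; 1000 replicates bound the type-I-error check at ±0.021
(3 MC SE around 0.05); recovery checks at $n = 10^4$ give haplotype-
frequency SEs an order of magnitude below the 0.05 tolerance.

## Shape of the repository

The package is organised as an analysis workflow: the numbered drivers
under `analysis/` narrate the study — design, simulated screen, parameter
table, LD, association — and write their tables under `results/`, while
every computation lives in the package functions so the test suite and
`scripts/acceptance.R` exercise the same code paths. The functions plus
these drivers are the intended interface; no separate shell CLI is
provided.

## Known limitations

* The analytic design assumes an error-free assay; dilution of one mutant
  template in a large pool can in reality cause false-negative pools. The
  simulator's `fn_rate` models this crudely (per-pool, not per-copy).
* LD estimates at a rare focal allele rest on a handful of carrier
  haplotypes; $D'$ is then highly unstable even though $r^2$ is stably
  small, and no permutation significance for $D'$ is provided.
* Exact Mann–Whitney p-values require tie-free data; heavily discretized
  traits fall back to the normal approximation even for tiny arms.
* The trait generator's noise families are stand-ins chosen to be
  realistically non-normal, not inferences about any particular cohort's
  distribution.
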