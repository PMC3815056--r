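---
title: "Methods: random-spore crossover mapping, tetrad analysis and the meiosis simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: random-spore crossover mapping, tetrad analysis and the meiosis simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sporemap)
```

`sporemap` analyses meiotic recombination in fungi from a random-spore
design: haploid spores are genotyped at ordered markers, each call being the
parental origin (`P1`/`P2`) of the spore's allele, and crossovers are read
off as switches of parental origin along the chromosome. This vignette is
the package's own account of the models and the choices behind them.

## Crossover calling and the two-point map

A crossover event is called wherever a spore's genotype switches between
two *consecutive non-missing* calls; the event is localized to the marker
span between them. When the span crosses missing calls the event still
counts toward the spore's crossover total, but not toward any single
interval's tally, because the interval in which the exchange happened is
ambiguous. This is why per-interval sample sizes vary: an interval's
denominator `n_informative` counts only spores with calls at both flanking
markers.

Genetic distance is the uncorrected two-point recombinant fraction,

$$\widehat{\mathrm{cM}} = 100 \cdot \frac{n_\mathrm{recombinant}}{n_\mathrm{informative}},$$

with no mapping-function (Haldane/Kosambi) correction, and the chromosome
map length is the plain sum of interval estimates. This matches
adjacent-marker map arithmetic in classical fungal genetics; it undercounts
double crossovers that fall inside a single inter-marker interval, a stated
limitation of the method rather than a defect of the implementation.

Each interval is classified by its physical-to-genetic ratio
(`kb_per_cM = physical span / cM`): below 15 kb/cM is a `hotspot`, above 75
kb/cM `cold`, between them `average`. Exactly 15 or 75 classifies as
`average`, a documented tie-break since "between" does not assign the
boundary; both thresholds are arguments of `classify_interval()` and
`interval_map()`. An interval with zero recombinants is `linked` — a class
label, not an infinite-tightness claim — and contributes 0 cM to totals.

## Strain comparison statistics

`compare_maps()` reproduces the standard battery:

* **per interval**: a two-sided Fisher exact test on the
  (recombinant, parental) × strain 2×2 table. The two-sided p is computed
  by probability ordering — the sum of hypergeometric probabilities of all
  tables with the observed margins no more probable than the observed one,
  with a relative tie tolerance of $10^{-7}$. This is the common
  convention; alternatives (doubling the one-sided p) exist and give
  slightly different values.
* **whole chromosome**: the chromosome treated as one interval — a Pearson
  chi-square on the 2×2 table of total crossover events versus
  informative-complement per strain. The exact table construction behind
  published whole-chromosome chi-squares is rarely stated; this
  reconstruction is flagged in the report so readers know it is a choice.
* **crossover distribution**: a chi-square test of independence on the
  intervals × strain event-count table with a Monte-Carlo p-value
  (default `B = 2000` samplings). Tables are drawn uniformly over all
  tables with the observed margins (Patefield's algorithm via
  `stats::chisq.test`), and the estimator is $(1 + \#\{X^2_{sim} \ge
  X^2_{obs}\})/(B+1)$, which cannot return zero. Intervals with no events
  in either strain drop out, as they carry no distributional information.

No multiple-testing correction is applied by default: per-interval p-values
are reported raw, as is conventional for these tables.

`pool_datasets()` gates the pooling of two same-cross datasets on
homogeneity: every per-interval Fisher p must exceed 0.1 and a combined
chi-square on the totals must exceed 0.05, otherwise pooling is refused
with the report attached. Exact tests on sparse tables are conservative,
so the gate rejects at most its nominal rate.

## Tetrad viability and the nondisjunction model

For dissected tetrads, the number of viable spores (4, 3, 2, 1, 0) is the
diagnostic signature of segregation failure. The model in
`nd_model_probs(v, d, m)` has three parameters:

* `d` — probability of meiosis I nondisjunction per meiosis. Both homologs
  travel to one pole: two disomic and two nullisomic spores, all
  aneuploid, hence zero viable spores.
* `m` — probability of meiosis II nondisjunction per MII division (each
  meiosis runs two). A failed division makes that daughter's two spores
  aneuploid.
* `v` — background death probability per euploid spore, independent across
  spores and meant to absorb strain-level inviability unrelated to
  segregation.

The class probabilities follow in closed form; for example the zero-viable
class is

$$P(0) = d + (1-d)\left[m^2 + 2m(1-m)v^2 + (1-m)^2 v^4\right].$$

The expected overall viability is $(1-d)(1-m)(1-v)$. The structural point
the model formalizes: a zero-viable tetrad arises from a *single* MI event
with probability $d$ but needs *two independent* MII failures,
$(1-d)m^2$ — `nd_zero_attribution()` returns the ratio $d/((1-d)m^2)$, which
is large whenever `m` is of the same order as `d`.

`nd_fit()` maximizes the multinomial likelihood by bounded L-BFGS-B from a
grid of starts (boundary fits such as all-4-viable data land cleanly on
zero estimates), with percentile bootstrap confidence intervals from
resampled tetrads. With only four degrees of freedom in the data and three
parameters, flat-likelihood fits are possible at small sample sizes; the
fit warns when an interval spans nearly the whole unit range.

## The meiosis simulator

The simulator exists so that every downstream stage is testable against a
known truth. A meiosis is simulated at the four-chromatid bivalent stage:

1. **Crossover positions.** Two modes. `renewal` places positions by a
   stationary gamma renewal process with mean count $\lambda$ per bivalent
   and shape $\nu \ge 1$: $\nu = 1$ is a Poisson process (no
   interference), larger $\nu$ regularizes spacings (positive
   interference). Stationarity is enforced by drawing the first spacing
   from the length-biased interval (Gamma($\nu+1$) times a uniform
   fraction), so crossover density is uniform along the chromosome.
   `interval_rates` draws an independent Poisson count per inter-marker
   interval, placed uniformly within it — the mode used to emulate
   localized subtelomeric hotspots.
2. **Chromatid choice.** Each crossover involves one chromatid from each
   homolog, chosen uniformly and independently (no chromatid
   interference). Meiotic products are constructed as paths through the
   four original molecules: a product switches to the partner molecule at
   every crossover involving the molecule it is currently travelling on,
   and since partners always belong to opposite homologs, each involving
   crossover flips the product's parental origin. (Swapping origin labels
   between products instead — a tempting shortcut — silently loses
   exchanges once strands are scrambled and biases the map downward; the
   path construction reproduces Haldane's function exactly at $\nu = 1$.)
3. **Obligate crossover.** When enabled, bivalents with zero crossovers
   are rejection-resampled. This is exact for the zero class, unlike
   truncating the count distribution.
4. **Segregation and viability.** MI separates the homolog centromeres, MII
   the sisters; nondisjunction and spore death follow the `(d, m, v)`
   model above. Aneuploid spores are always inviable. Genotypes of viable
   spores are sampled at the marker positions, and each call is lost with
   the missing-call probability.

A consequence of drawing crossovers at the four-chromatid stage is the
factor-of-two chromatid dilution: a spore sees a given crossover with
probability ½, so the expected total map length is $50\lambda$ cM and the
per-interval recombinant fraction under a Poisson count with mean $r$ is
$(1-e^{-r})/2$ — the identities the test suite checks.

All randomness flows through R's global RNG, seeded once per
`simulate_population()` call from the mandatory `SimConfig` seed, so every
simulated dataset is a pure function of its configuration.

## Study-condition defaults

The built-in study conditions (`cc_chromosome()`, `cc_crossover_model()`,
`cc_sim_config()`, `study_cross()`) emulate a two-strain mapping design:
~100 random spores per cross genotyped at 14 markers spanning chromosome 3
and 10 markers in the chromosome 8 hotspot region, plus 100 dissected
tetrads per strain. Interval physical sizes and genetic sizes are a
synthetic reconstruction chosen once: per-interval kb/cM ratios follow the
published interval classes, wild-type chromosome 3 sums to ~0.93 Morgans
against ~1.6 in the mutant-like strain, and hotspots sit subtelomerically.
Tetrad rates — wild type $(d, m, v) = (0.01, 0.005, 0.0635)$, mutant
$(0.15, 0.02, 0.125)$ — were solved from $(1-d)(1-m)(1-v)$ to give overall
viabilities near 92% and 73% with ~1% and ~16% zero-viable tetrads. The
missing-call rate of 3% makes per-interval sample sizes "slightly less
than" the number of genotyped spores, as real PCR failure does. These are
emulation parameters, not measurements: passing tests show the analysis
recovers the truth of data *with this statistical structure*; they cannot
validate rates in any real organism. Real data additionally contain gene
conversion tracts, segregation distortion and marker-specific failure
modes, none of which the generator produces.

## The synthetic gene record

The mutation-annotation component ships a fully synthetic gene
(`nbs1_gene()`), generated in code: 3528 bp, 10 introns totalling 528 bp,
a 3000-bp coding region and a 999-residue protein, engineered so the five
classical allele edits at their published gene-local coordinates yield
their published protein effects (S43F; a stop at residue 570; an
A288V-plus-immediate-stop frameshift; and a destroyed intron-5 acceptor
whose two splice outcomes truncate after residues 328 and 399). Everywhere
else the coding sequence is a fixed cycle of sense codons. Coordinates are
1-based and gene-local with position 1 the A of the start codon; the S43F
anchor (edit at bp 188–189 landing in codon 43) is asserted in the tests
and pins the convention. The record deliberately carries no sequence
information beyond the published coordinates, so analyses that depend on
the real deposited sequence (e.g. the ~110 kDa predicted mass) are not
asserted against it.

Translation uses the standard nuclear code and stops at the first in-frame
stop; `ATG TAA` therefore yields the one-residue protein `M`, and molecular
weights are sums of average (not monoisotopic) residue masses plus one
water, matching how rounded kDa figures are usually quoted. For truncating
mutations both conventions found in the literature are surfaced:
`aa_position` is the residue replaced by the new stop and
`truncated_length = aa_position - 1` is the mutant protein length.

## Numerical choices and degenerate inputs

* Fragment-call acceptance requires a peak height strictly greater than
  500 units; a height of exactly 500 is rejected (acceptance is "more
  than 500"). Zero or multiple accepted peaks reject the sample; an
  accepted peak matching neither parental size within the 1-bp default
  tolerance yields `NA` with a warning, never silently.
* `fisher_exact()` applies a $1+10^{-7}$ relative tie tolerance in
  probability ordering, matching common practice and making enumeration
  comparisons exact.
* Monte-Carlo p-values use $(1+x)/(B+1)$ and are reproducible given a
  seed; `B < 1` is an error.
* Empty genotype files, duplicate spore ids and unknown genotype tokens
  are hard errors that name the offending cell; all-`NA` spores are
  allowed and flagged.
* An all-zero crossover model with an obligate-crossover requirement is
  rejected as unsatisfiable rather than looping forever.
* Zero-tetrad viability tables and empty germination-spot lists are
  errors, not `NaN`s.

## Problem sizes

The test suite validates the exact tests by exhaustive enumeration (all
2×2 tables with $N \le 40$; 2×5 tables with $N \approx 30$), Monte-Carlo
calibration with 500 null tables at $B = 2000$, and the simulator against
closed forms at 10,000 meioses; parameter recovery uses 10,000 simulated
tetrads with 1000 bootstrap replicates. These sizes were chosen as the
smallest at which the 3-standard-error bounds used throughout are sharp
enough to catch the classes of error the suite is designed to detect.
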