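---
title: "Detecting recent introgression with haplotype-similarity scans"
author: "introscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting recent introgression with haplotype-similarity scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(introscan)
```

## The model and its assumptions

`introscan` detects recent gene flow from a *donor* population into a
*recipient* population using phased, imputed SNP genotypes.  The design
requires four population roles:

* **recipient** — the population tested for introgression;
* **donor** — the putative source of gene flow;
* **ancestor proxy** — a related population standing in for the
  recipient's un-admixed ancestor (in the chicken setting that motivated
  the package, a wild-relative breed);
* **control** (optional) — a second ancestral population used to subtract
  signals attributable to shared ancestry rather than recent gene flow.

The genome is cut into non-overlapping windows of `k` consecutive SNPs
(default `k = 5`, sweep 2–10 supported; a trailing window with fewer than
`k` SNPs is dropped, and windows never span chromosome boundaries).
Within a window, each population's haplotypes are tabulated as exact
`k`-character allele strings — no mismatch tolerance, because the unit of
evidence is the *distinct haplotype*.  Similarity between two populations
is the Pearson chi-square on the 2 × H table of pooled distinct
haplotypes, with expected counts from the marginals (the standard
homogeneity completion); pooled-zero columns are dropped and no
continuity correction is applied, since inference comes from a
permutation null rather than the chi-square distribution.  The scan
statistic

$$\Delta\chi^2 = \chi^2(\text{anc}, \text{rec}) - \chi^2(\text{rec}, \text{don})$$

is negative wherever the recipient resembles its ancestor more than the
donor — the genome-wide norm — and positive where local haplotype
structure has been replaced by donor material.

Assumptions worth stating: input is biallelic, complete (imputed) and
phased; sites are sorted by position; the three scan populations are
sampled from comparably processed data (the permutation null removes
population labels, not genotyping artifacts).

## Permutation inference and candidate calling

For each window, individuals are randomly reassigned among the three role
populations `B = 1000` times, holding each population's size fixed and
keeping both haplotypes of an individual together (preserving
within-individual phase).  The empirical p-value is
$p = (n + 1)/(B + 1)$, where $n$ counts permuted $\Delta\chi^2$ values at
or above the observed one — a one-sided test in the introgression
direction.  Windows with `p < 0.001` **and** positive $\Delta\chi^2$ are
candidates; with `B = 1000` a candidate must beat all 1,000 permutations.
Following the original design the threshold is a fixed `alpha` with no
multiple-testing correction; `alpha` is exposed as a parameter.

Two computational details:

* **Early stopping** (`early_stop = TRUE`): a window's permutation loop
  may stop as soon as enough exceedances have accrued to rule out
  candidacy at `alpha`.  Candidate decisions are identical to the full-`B`
  run; p-values of stopped windows become conservative estimates based on
  the permutations actually run (reported in `b_used`).
* The permutation shuffles across *all three* populations.  A variant that
  holds one population fixed is conceivable but is not implemented.

Candidates that are also candidates in the control population's own scan
(run with the control as "recipient" against the same ancestor proxy and
donor) are removed window-exactly.  Adjacent surviving candidates merge
into regions; the introgressed genome fraction is reported both in bp of
windowed genome and in windows, since either denominator is defensible.

## Clustering and annotation summaries

The Wald–Wolfowitz runs test asks whether candidate windows cluster:
with $n_1$ candidate and $n_2$ non-candidate windows and $R$ observed
runs, $\bar R = 2n_1n_2/(n_1+n_2) + 1$,
$S_R^2 = 2n_1n_2(2n_1n_2-n_1-n_2)/((n_1+n_2)^2(n_1+n_2-1))$ and
$Z = (R-\bar R)/S_R$ is compared to the standard normal; $|Z|>1.96$
rejects randomness at 5%, and negative $Z$ (fewer runs) means clustering
into introgression islands.  Windows are ordered within chromosomes and a
chromosome boundary always ends a run; one genome-wide $Z$ is reported
(matching a single-statistic-per-population summary) along with
per-chromosome values.

Gene-density correlation bins the genome into 1 Mb bins, counts candidate
windows and annotated genes per bin — a feature counts in every bin it
overlaps — and reports Pearson's r with its two-sided t-based p-value.
Constant counts make r undefined and raise an error rather than a silent
`NA`.

IBD summaries consume precomputed segments (refined-IBD-style tables),
keep those with LOD > 3 and length ≥ 1 cM under a flat 300 kb/cM map, sum
shared length per population pair and divide by the product of the two
population sizes (Mb per individual pair).

## Diversity indices

* `Pn`: fraction of sites with within-population MAF above 0.05, computed
  on the population slice only (sites monomorphic genome-wide but variable
  locally count).
* ROH: maximal runs of homozygous genotypes allowing at most one
  heterozygous and five missing calls, qualifying at ≥ 50 SNPs *or*
  ≥ 500 kb.  The caller is a direct greedy maximal-run scan (verified
  against a brute-force enumerator in the tests), not a
  scanning-window heuristic; both the mean segment length and the mean
  per-individual total are reported since "mean ROH" is ambiguous.
* Haplotype diversity `H = N/(N-1) (1 - sum x_i^2)`.  **Choice of N**: the
  frequencies $x_i$ are haplotype frequencies, so `N` is the number of
  haplotypes in the window (two per diploid).  Using individuals instead
  would break the identity `H = 1` when all haplotypes are distinct, which
  we treat as decisive.  Mean window `H` rises with window size and
  saturates around 10 SNPs, which is why window sizes beyond ~10 add
  little.

## XP-EHH selection scan

EHH at distance *s* from a core SNP is the probability that two randomly
drawn haplotypes are identical at every site from the first flanking site
through *s*; `EHH = 1` at the core (the core allele itself does not
partition the haplotypes, matching the cross-population statistic's
site-level formulation) and is non-increasing outward.  iHH is the
trapezoidal integral of EHH over genetic distance under the flat
300 kb/cM map, both directions summed, truncated at the first point where
EHH drops below 0.05 (integration runs to the chromosome edge when the
curve never drops).  Cores where either population's iHH is zero are
dropped with a message.  The raw statistic `ln(iHH_A/iHH_B)` is
z-standardized over all scored cores genome-wide (per-chromosome
standardization is a defensible alternative; genome-wide was chosen as
the default universe and is what the tests pin down), p-values are
two-sided from the standard normal by default (a one-sided mode and a
per-core direction are provided so "selection in B" can be filtered), and
windows with ≥ 3 significant cores (p < 0.05) are called selected.
Overlap between selection calls and introgression candidates is
summarized as four window-based percentages.

## D-statistic

The frequency-based four-taxon statistic on the ordering (ancestor proxy,
recipient, donor, outgroup) uses site terms
`BABA = p1 (1-p2) p3 (1-pO)` and `ABBA = (1-p1) p2 p3 (1-pO)` and

$$D = \frac{\sum(\text{BABA} - \text{ABBA})}{\sum(\text{BABA} + \text{ABBA})}$$

**Sign convention.**  With this numerator a *negative* D (and jackknife Z)
indicates excess derived-allele sharing between the recipient and the
donor — the introgression signal — mirroring the convention of the
original analysis this package follows.  Swapping P1 and P2 negates D
exactly, and monomorphic sites contribute nothing.  Z comes from a
delete-one jackknife over contiguous blocks (default 500 sites; for
LD-free synthetic data smaller blocks give a better-behaved Z, and the
calibration tests use 100).  An outgroup population defines the ancestral
state by its major allele, with sites more than 10% polymorphic in the
outgroup dropped; with no outgroup the REF allele is taken as ancestral,
which is exact for the simulator's output where REF encodes the ancestral
state.

A desk-scale caveat established during development: under the forward
model below, population divergence is deep (~10 N generations), so
without migration the populations share almost no ancestral polymorphism
and there are essentially no ABBA/BABA-informative sites — D is
degenerate, not merely noisy.  The D null calibration therefore runs on
the mosaic generator (which retains shared polymorphism by construction),
while the sign expectation under gene flow is verified on forward
migration simulations, where migration itself creates informative sites.

## The forward simulator

`simulate_forward()` implements a discrete-generation Wright–Fisher model
with per-individual Poisson recombination, infinite-sites mutation
(continuous positions), migration and multiplicative selection; all
randomness flows through R's RNG so runs are reproducible under a seed.

The default configuration *is* the validation design: 1 Mb genome,
mutation rate 1e-8 and recombination rate 3e-7 per bp per generation, an
ancestral population P1 of 5,000 diploids burnt in for 50,000
generations, a donor population P2 of 2,000 splitting from P1 and
diverging without contact for 50,000 generations, unidirectional
migration P2 → P1 over the final 200 generations at per-generation rate
`m` ∈ {0.001, …, 0.009}, selection coefficients s ∈ {0, 0.001, 0.002},
and 100 diploids sampled per population.  Donor-origin tracts are tracked
exactly from migration start, so every sampled recipient haplotype
carries known truth and the true donor fraction is a bookkeeping
identity, not an estimate.

Design choices that the base model leaves open, fixed once here:

* **Ancestor proxy.**  The two-population validation design has no third
  population, but the scan requires an ancestor proxy.  It splits from
  the recipient lineage 2,000 generations before sampling (`anc_split`),
  giving Fst ≈ 0.2 to the recipient — a wild-relative level of
  divergence, far smaller than the recipient–donor divergence.  This
  matters: a proxy that splits only at migration start is statistically
  the recipient itself, `chi2(anc, rec)` collapses to noise, and
  $\Delta\chi^2$ can only turn positive where donor ancestry exceeds
  ~50% locally, crippling sensitivity.
* **Migration orientation**: donor into recipient only ("P2 admixes with
  P1"), per-child (both parents drawn from the source population).
* **Selection**: "beneficial SNPs covering 0.1% of the genome" is
  implemented as 0.1% of donor-private polymorphic sites (at least one)
  designated at migration start, each copy multiplying recipient fitness
  by (1 + s) during the migration phase — multiplicative genic selection,
  since no dominance model is stated.
* **Rescaling**: `rescale_factor = Q` divides population sizes and
  generation counts by Q and multiplies mu, rec, m and s by Q, preserving
  N·mu, N·rec, N·m, N·s.  Q = 20 keeps the donor population at 100
  diploids so the stated sample sizes remain attainable; any rescaling
  that pushes a population below 50 diploids errors out as over-rescaled.
* **Burn-in replacement** (`init = "sfs"`): the validation script seeds
  the ancestral population with standing variation drawn from the neutral
  site-frequency spectrum (`P(count = i) ∝ 1/i`) followed by 2 N
  generations of forward linkage equilibration, instead of the full
  forward burn-in.  The subsequent 50,000-generation (10 N) divergence
  phase exceeds the coalescent depth of either population, so
  initialization artifacts are erased for all but the deepest shared
  variation.  The configuration records which mode was used.

## What the generators emulate — and what they do not

The mosaic generator (`mosaic_generator()`) draws site-independent
haplotypes from Balding–Nichols-diverged allele frequencies and plants
contiguous donor tracts covering an exact fraction of sites.  It emulates
population differentiation and block-like introgressed ancestry with
perfectly known truth, which is what calibration (exchangeable null at
`divergence = 0`) and precision/recall checks need.  It does **not**
emulate linkage disequilibrium within populations, allele-frequency
spectra of real chips, ascertainment bias, phasing or imputation error,
or drift of tract frequencies — so a green calibration test establishes
correctness of the permutation machinery, not robustness to chip
artifacts.  The forward simulator adds realistic LD, drift and tract
length distributions at desk scale, but a 1 Mb genome and rescaled
population sizes mean its site density and diversity are not those of a
genome-wide chip panel.

## Numerical choices and degenerate inputs

* Internal coordinates are 0-based half-open everywhere; conversion
  happens only at the VCF/GFF boundary.  Sites are re-sorted (with a
  message) if needed; duplicated positions on a chromosome are an error.
* Missing genotypes after load are a hard error ("unimputed input");
  imputation is declared upstream.  Unphased genotypes error by default
  or drop their site under `unphased = "drop"`.
* Empirical p-values live on the lattice `(n+1)/(B+1)`; ties between
  permuted and observed $\Delta\chi^2$ count toward `n` (conservative).
* `qc_filter_sites` removes sites with MAF < 0.05 (strict) or call rate
  < 95%; removing every site is an error, not an empty result.
* Degenerate runs-test sequences (a single class) and windows with a
  zero-sample population raise errors naming the problem.
* The random seed covers every stochastic stage; `run_pipeline` seeds
  once and runs stages in a fixed order, so identical configurations
  produce identical outputs.

## Known limitations

* **Detection floor of the statistic.**  $\Delta\chi^2 > 0$ requires the
  recipient's window spectrum to sit closer to the donor than to the
  ancestor proxy.  With a realistically diverged proxy this happens well
  below donor-majority ancestry, but windows carrying only a few percent
  donor haplotypes are generally not called: under the stated migration
  design (200 generations at m ≥ 0.001, hence ≥ ~15–18% genome-wide donor
  ancestry, with little local ancestry drift) the validation sweep can
  only demonstrate reliable detection down to the smallest attainable
  fraction, ~15–18%, not probe the region near 5%.
* The control-population exclusion is window-exact, not bp-overlap, and
  assumes the control was scanned on the same window index.
* XP-EHH uses a flat genetic map (300 kb/cM) and genome-wide
  standardization; fine-scale recombination-rate variation will shift
  individual scores.
* The D-statistic's block jackknife assumes blocks larger than the LD
  scale; on dense real data the 500-site default should be revisited
  against the panel's SNP spacing.
* The forward simulator is a validation instrument, not a chromosome-scale
  population-genetics engine; it has no demographic changes beyond the
  stated model, no dominance, and no recurrent mutation (infinite sites).
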