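---
title: "Reduced-representation genotyping: models, filters and scans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reduced-representation genotyping: models, filters and scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rrlpopgen)
```

## What this package models

Reduced-representation library (RRL) sequencing cuts genomic DNA with a
restriction enzyme, size-selects the fragments, and sequences only that
reproducible sliver of the genome across many individuals. Because SNPs
are discovered and genotyped in the same read data, allele frequencies
can be estimated directly, without the ascertainment bias of a separate
discovery panel. `rrlpopgen` implements the computational side of such a
study end to end:

1. **Design** — in-silico digestion of a reference genome and
   fragment-size selection (`digest()`, `select_fragments()`,
   `fragment_profile()`, `window_sensitivity()`).
2. **Simulation** — a two-population diploid cohort with known truth
   (`simulate_rrl_cohort()` and its parts), so every downstream stage is
   testable without any external data.
3. **Genotype calling** — a hard-filter caller using fixed
   allele-balance cut-offs and a binomial genotype-likelihood caller
   (`call_population()`).
4. **Filtering** — the population-based SNP filter and target-efficiency
   accounting (`population_filter()`, `target_efficiency()`).
5. **Comparison** — overlap, concordance, intersection and validation
   scoring between call sets (`site_overlap()`, `genotype_concordance()`,
   `intersect_callsets()`, `score_validation()`).
6. **Inference** — site heterozygosity, minor-allele-frequency spectra,
   singletons/private SNPs, and the sliding-window allele-frequency
   differential scan (`sliding_window_scan()`).

## In-silico digestion

Only palindromic blunt-end cutters (4–6 bp sites) are modelled, so a
single forward-strand scan enumerates every cut. All overlapping
occurrences of the site generate cuts (physical digestion is
exhaustive), matching is case-insensitive, and a site never matches
across an `N`: assembly gaps are not sequencable targets, so they are
cut-opaque. Fragments tile each sequence exactly — the suite asserts
`sum(widths) == sequence length` on every digest.

Size selection is inclusive on both ends: a "104–123 bp" window keeps
lengths 104 through 123. The genome fraction uses the full sequence
length (including `N`) as denominator. Soft-masked (lowercase) content
is carried per fragment as a repetitive-content proxy, since visual
repeat inspection is not reproducible.

Coordinates are `GRanges` (1-based, closed) inside R; BED output is
produced by `rtracklayer`, which performs the only conversion to the
0-based half-open on-disk convention.

## The synthetic cohort

The generator emulates the statistical structure the analysis assumes,
not the sequencing chemistry:

* **Genome** — random A/C/G/T with recognition sites planted at known
  positions (accidental occurrences are scrubbed first), so digest
  output is known exactly. `simulate_target_genome()` plants site pairs
  a fixed distance apart, giving evenly spaced in-window fragments.
* **Cohort** — two populations of 15 and 16 unrelated individuals by
  default, the typical scale of a wild-population RRL study.
* **Genotypes** — Hardy–Weinberg draws: two Bernoulli(*p*) allele
  copies per individual, with *p* the population's per-site
  alternative-allele frequency. Background frequencies default to
  Uniform(0.05, 0.95), shared between populations (no drift between
  them), so the background allele-frequency differential is pure
  sampling noise.
* **Read counts** — per (site, individual) depth is Poisson with mean
  40, near the high coverage of a well-powered RRL study; each read
  reports the allele of a uniformly chosen chromosome copy, flipped
  with a symmetric error probability. Counts are quality-passing by
  construction: base/mapping-quality filtering is modelled as already
  applied, because the callers under study consume post-filter pileups.
* **Sweeps** — `plant_sweep()` sets the frequency differential of SNPs
  inside a region to *d* via `(1 + d)/2` and `(1 − d)/2`; `d = 1`
  fixes alternative alleles in opposite populations. A zero
  differential is a no-op by definition.

SNPs are placed only inside target regions (RRL sequencing yields no
data elsewhere). Not emulated: linkage disequilibrium, indels, mapping
artefacts, platform-specific depth profiles, or coalescent demography —
so passing tests show that the *pipeline arithmetic* is right under the
assumed model, not that the model captures every property of real data.

## Genotype calling

Both callers work from the same `(ref_count, alt_count)` pairs and share
depth gates: depth below 10 or above 1000 is missing.

**Hard filter.** With `f = alt/(ref + alt)`: `f < 0.15` is homozygous
reference, `0.20 ≤ f ≤ 0.80` heterozygous, `f > 0.85` homozygous
alternative. The borderline zones `[0.15, 0.20)` and `(0.80, 0.85]` are
conservatively missing; band edges are assigned to the conservative
side, with the heterozygous band closed on both ends. No genotype
quality is attached — a cut-off rule has none — and consequently no GQ
filter applies.

**Likelihood caller.** Binomial likelihoods
`L(homref) = B(alt; n, e)`, `L(het) = B(alt; n, ½)`,
`L(homalt) = B(alt; n, 1 − e)`, maximum-posterior call, phred-scaled
GQ capped at 99, and a `GQ ≥ 10` gate. Two prior modes exist:

* `af_prior = "estimate"` (default in `call_population()`): a per-site
  alternative-allele frequency is estimated from the pooled counts
  (with a half-read pseudocount) and converted to Hardy–Weinberg
  genotype priors. This emulates multi-sample calling, where the
  cohort informs each individual's prior.
* `af_prior = "genotype"`: single-sample priors
  `{1 − θ − θ², θ, θ²}` with θ the heterozygosity prior (default
  0.001).

The choice matters for the central caller-bias phenomenon. At low
depth a true heterozygote often shows a skewed allele balance (say 2
alt reads in 12), which the hard filter miscalls homozygous or drops
as borderline. A likelihood caller with a *population* prior knows the
site is polymorphic at intermediate frequency and keeps calling
heterozygotes over a wider balance range; with only a single-sample
θ = 0.001 prior it is, on the contrary, even more reluctant than the
hard filter to call a heterozygote. Since the multi-sample mode is how
probabilistic callers are run in cohort studies, it is the default,
and under it the hard filter's heterozygote call rate is strictly
below the likelihood caller's at mean depth 12 — the systematic
het-versus-hom discordance direction the comparison module is built to
quantify. Notably, because both callers here see *identical* counts,
both-called discordances are rare; in real multi-caller comparisons the
callers also disagree about which reads to count, which inflates
discordance rates far beyond what shared counts produce.

Sites whose third-allele reads total at least 2 are flagged
multi-allelic and removed by the population filter (the analysis is
strictly biallelic). A site where every called individual is homozygous
reference is flagged non-variant but retained for lookup, since a
missing call cannot distinguish "reference" from "not sequenced".

## Population filter and popgen statistics

A site is kept only if every population has at least 8 called
individuals (≥ 16 chromosomes), which keeps direct allele-frequency
estimates meaningful; frequencies are computed from called genotypes
only. Observed site heterozygosity is the called-het fraction. The
differentiation statistic is the allele-frequency differential
`D = (|p₁ − p₂| + |q₁ − q₂|)/2`, which for biallelic sites collapses to
`|p₁ − p₂|` (asserted algebraically on a frequency grid).

The scan tiles each chromosome with 100 kb windows advancing by 25 kb,
anchored at position 1. Trailing partial windows are included so
chromosome ends are not lost; excluding them is one `exclude`-pattern
away, which is also how unplaced `*_random` scaffolds are dropped.
Windows with mean `D > 0.95` over at least 2 SNPs are outliers —
candidate divergent-selection regions. Window means weight SNPs
equally (not by coverage).

Singletons (exactly one alternative-allele copy among called
genotypes) are computed in two scopes, overall and per population,
because summary tables use both senses; the per-population percentage
uses sites polymorphic within that population as denominator, which
keeps private-SNP counts (polymorphic in one population, monomorphic
in the other) consistent with it. MAF densities use a Gaussian kernel
with Silverman's bandwidth; formal density-equality testing is out of
scope.

## Numerical choices and degenerate inputs

* Hard-filter band comparisons use floating `alt/depth` against the
  band edges; at every exactly-representable tie (e.g. 3/20 = 0.15)
  this agrees with exact integer arithmetic, which the suite verifies
  by exhaustive enumeration of all count pairs to depth 60.
* Posterior ties in the likelihood caller (possible only in degenerate
  zero-information cases) break toward homozygous reference; zero
  depth is missing via the depth gate before any tie can matter.
* GQ is `round(−10·log10(1 − posterior))`, capped at 99, with the
  complement floored at 1e−10 to avoid `-Inf`.
* Percentages in validation tables are reported raw; printed tables
  round half-up (`round_half_up()`), matching how published percentage
  tables are typeset.
* Empty call sets filter to an empty SNP table with a warning;
  individuals with zero high-quality bases get `NA` efficiency with a
  warning.

## Problem sizes

The shipped tests run the full pipeline at the study's own scale where
that is cheap (a 2 Mb chromosome, 31 individuals, 450 SNPs, depth 40
for sweep recovery; 200,000 sites × 31 individuals for the discordance
classification in `scripts/acceptance.R`) and at reduced sizes for
unit-level properties. The digest is cross-checked against a naive
scanning oracle on 1,000 random sequences, and caller behaviour against
exhaustive rule-table enumeration.

## Known limitations

* Only palindromic blunt-end single digests; no partial digestion,
  methylation sensitivity, or sticky ends.
* No read-level simulation (FASTQ), mapping, or indel handling; the
  pipeline starts at quality-passing allele counts.
* The likelihood caller is deliberately minimal — it is a stand-in for
  probabilistic callers as a *class*, built to study caller
  disagreement, not to reproduce any specific tool's internals.
* With both callers fed identical counts, absolute discordance rates
  are lower bounds on what heterogeneous read-counting pipelines show.
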