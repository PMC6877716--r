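---
title: "Consensus SNP genotyping from environmental DNA: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus SNP genotyping from environmental DNA: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(ednasnp)
```

## The problem

Tissue sampling of bivalves for SNP genotyping is invasive: the shell must
be forced or the animal anaesthetised, and sampling can kill valuable
broodstock. An alternative is to hold an animal in a small volume of clean
seawater, recover the DNA it sheds (environmental DNA, eDNA) by filtration,
and genotype that. The catch is that eDNA is dilute and degraded, so
genotype calls from single reactions are unreliable; reliability is bought
with replicate reactions and a consensus rule, and depends strongly on the
DNA extraction method and on how the template is diluted before and after
the multiplex pre-amplification (STA) PCR.

`ednasnp` implements the full analysis around that workflow:

1. **Panel selection** — rank candidate bi-allelic SNPs by mean minor
   allele frequency (MAF) across discovery populations and keep the top
   *k*. High-MAF SNPs (> 0.2 by convention) discriminate best between
   individuals for parentage assignment; the 0.2 threshold is reported as
   an annotation, never applied as a filter.
2. **Genotype calling** — convert per-reaction two-channel fluorescence
   intensities into calls over {AA, AB, BB, NOCALL} by clustering within
   assay × dilution strata and labelling clusters from tissue reference
   reactions run at the equivalent dilution.
3. **Concordance** — score every replicate eDNA reaction against the
   tissue-derived reference genotype: the *call rate* of a water sample.
4. **Replication simulation** — estimate, by subsampling the available
   replicates, how consensus accuracy grows with the number of replicate
   reactions one is willing to pay for.
5. **Synthetic data** — a generator that emulates the study design
   end-to-end, so the whole pipeline is testable without laboratory data.

## Genotype calling

Within one assay × dilution-scheme stratum, both intensity axes are
min–max rescaled to [0, 1] (an axis that is constant across the stratum
cannot be rescaled; it is set to 0 and flagged). Dilution changes the
intensity scale, so strata are never pooled across schemes. Whether
clustering runs on normalized or raw intensities is a configuration
switch (`normalize` in `call_dataset()`); normalized is the default.

k-means is fitted for k = 1..3 (three genotype clusters for a bi-allelic
SNP) and k is chosen by average silhouette width, with a floor of 0.5:
below the floor, or when the silhouette is undefined, the stratum
collapses to k = 1 and — if the single cluster is diffuse (mean distance
to centroid above 0.2 normalized units) — is flagged
`"no identifiable clusters"`. The floor-and-flag mechanism is the
automated stand-in for an analyst rejecting a failed assay by eye;
automation needs an explicit criterion where a human used judgement.
Restarts (`nstart = 10`) run under deterministic sub-seeds, so fitting is
reproducible.

Centroids are labelled by the majority reference call of the tissue
reactions nearest to them. Six individuals cannot guarantee that all
three genotypes segregate at every SNP, so centroids capturing no tissue
reaction fall back to intensity geometry: highest allele-1 signal AA,
highest allele-2 signal BB, remainder AB — except centroids within 0.25
normalized units of the origin. A near-origin cluster is where
no-template controls and failed amplifications sit, so it is labelled
NOCALL rather than being mistaken for a missing genotype. All fallbacks
and label conflicts are QC-flagged.

Each reaction then takes the genotype of its nearest centroid, provided
it lies within the **no-call radius**: 3 × the median distance of tissue
reactions to their nearest centroid, but never less than half the minimum
inter-centroid gap. The second term matters: the first is a pure noise
quantile, and on clean data about 0.2% of genuine cluster members fall
beyond any fixed small multiple of the median — a radius below half the
cluster gap would no-call reactions that are unambiguously nearest one
centroid. Both the multiplier and a fixed radius override are exposed in
the configuration. Reactions beyond the radius, and reactions nearest a
NOCALL-labelled centroid, are no-calls. Controls are excluded from
fitting (they are contamination sentinels, not samples) but are run
through the calling rule and flagged if they produce a genotype.

Platform exports that already carry calls (rows with calls but no
intensities) bypass this module untouched.

## Concordance

The tissue reference for a sample × scheme is, per assay, the majority
tissue call after excluding no-calls; assays whose reference is
all-NOCALL or tied cannot anchor a comparison and are dropped with a
warning. Every replicate eDNA reaction on a scored assay then counts
once: a match if it equals the reference, otherwise a mismatch, with
NOCALL kept in the denominator as non-matching. A no-call cannot
"match": that reading is the only one under which observed call rates
can fall as low as ~20%. The per-sample summary uses the unweighted mean
and the n−1 sample standard deviation, reported in percent. Water samples
extracted by different methods belong to different schemes and are scored
as separate results.

Whether reactions on assays *without* a usable reference should still
occupy the denominator is genuinely ambiguous; `unscored_assays =
"exclude"` (default) drops them, `"count_as_mismatch"` keeps them.

## Replication simulation

For each genotype (individual × SNP) with *n* replicate calls, a scenario
at replication level *r* draws *r* replicates without replacement —
simulating having run only *r* physical reactions — and forms the
consensus: drop NOCALLs, then take the strictly most frequent genotype.
Equal-frequency conflicts give no consensus and score incorrect; so does
a subsample with nothing callable left after dropping NOCALLs, the
conservative reading of "majority excluding no-calls". Accuracy is the
proportion of genotypes whose consensus equals the tissue reference,
pooled over all genotypes of a scheme.

Two estimators run side by side:

* `run_simulation()` — the Monte-Carlo design: 100 scenarios per scheme ×
  level by default, each scenario drawing, independently for every
  genotype, one of the `choose(n, r)` subsets uniformly at random
  (equivalent to sampling r replicates without replacement). Every
  scenario has a counter-derived sub-seed and is independently
  reproducible. A `shared_subset` switch instead draws one subset index
  per scenario shared across genotypes, since the original 100-scenario
  design does not state which convention it used; independent per-genotype
  draws are the default as they give the estimator strictly smaller
  variance at the same cost.
* `exact_consensus_accuracy()` — full enumeration of all `choose(n, r)`
  subsets per genotype: the exact expectation the scenarios estimate, at
  negligible cost for n ≤ 8. At r = n the two coincide identically.

## The synthetic generator

`simulate_study()` draws true genotypes under Hardy–Weinberg equilibrium
at the panel MAFs, then emits reactions for the default design: 6
individuals × 16 SNPs × 8 dilution schemes (D1–D4 column extraction,
C1–C4 Chelex), 6 replicate eDNA reactions and 3 tissue reference
reactions per individual × SNP × scheme, plus one no-template control per
assay × scheme. Each reaction's call is the truth perturbed by the
scheme's error model — NOCALL with probability `p_nocall`, else a
uniformly chosen wrong genotype with probability `p_miscall` (no miscall
spectrum is modelled; nothing downstream depends on which wrong genotype
appears) — and its intensities are drawn around the emitted call's
cluster centroid (AA on the allele-1 axis, BB on allele-2, AB
intermediate, NOCALL at the origin) with the scheme's
separation-to-noise ratio. Genotypes are labelled abstractly (AA/AB/BB)
rather than by dye, since dye identity is irrelevant to every statistic
computed here. Tissue reactions get their own near-perfect error model:
tissue is the ground truth the whole analysis is anchored to.

The per-scheme error rates are deliberately phenomenological — no PCR
kinetics, copy numbers or filtration recovery are modelled — and the
default values are illustrative, since no per-dilution no-call/miscall
decomposition is published. They were fixed once, as follows: the two
best schemes are anchored so that their per-replicate correct
probabilities `(1 − p_nocall)(1 − p_miscall)` equal the observed
single-replicate consensus accuracies (D2 ≈ 0.994, C1 ≈ 0.958 — at r = 1
the expected consensus accuracy *is* the per-replicate correct
probability), and the remaining schemes span the observed degradation
(all other Chelex schemes below 90%, worst around 20%). Cluster
separations stay in the identifiable range (5–12 noise SD): in the
underlying study clusters remained identifiable except for two
non-polymorphic assays, the dilution-dependent degradation being carried
by dropout and miscalls, not by cluster collapse. An early draft used
separations down to 3, which made k-means itself fail for the poor
schemes and double-counted degradation already encoded in the error
rates; it was revised once and not revisited. What passing tests on this
generator show is that the *analysis* is correct under its assumed error
structure; they cannot show that real eDNA errors are independent across
replicates, uniform across individuals, or free of the allele-specific
dropout that makes heterozygotes systematically harder — on real data,
expect heterozygote-biased miscalls the generator does not produce.

One global integer seed expands deterministically into per-stage,
per-scheme and per-scenario substreams (a multiplicative string hash into
[0, 2^31)), so any stage can be rerun in isolation and two runs of the
same configuration are byte-identical.

## Numerical and design choices, in one place

* Silhouette floor 0.5; k = 1 dispersion flag at 0.2; near-origin
  centroid guard at 0.25 (all in normalized units).
* No-call radius: `max(3 × median tissue distance, half the minimum
  centroid gap)`, floor 0.05.
* Panel ties broken lexicographically by SNP id, making selection
  invariant under input permutation.
* Mean MAF is unweighted across populations (population sample sizes are
  not modelled).
* Tissue references are emitted per dilution scheme, so every stratum
  contains the references it is labelled from.
* Consensus ties and empty consensus sets score incorrect; subsampling is
  without replacement.
* CSV (RFC 4180, UTF-8, "." decimal) everywhere; readers fail fast with
  line numbers and never return partial tables.

## Problem sizes

The test suite exercises the closed-form recoveries at 360–480 generated
replicate calls per case, oracle-vs-estimator agreement at up to 10,000
scenarios over 20 genotype pools of 8 replicates, and the end-to-end
recovery on two clean schemes of the full 6 × 16 design; the default
study (8 schemes, 6912 eDNA reactions, 100 scenarios per scheme × level)
runs in a few seconds.

## A worked run

```{r, eval = FALSE}
cfg <- pipeline_config(out_dir = "ednasnp-out", seed = 1)
bundle <- run_pipeline(cfg)
bundle$call_rate_summary
bundle$simulation$summary
plot_replication_accuracy(bundle$simulation)
```

## Limitations

Beyond the generator caveats above: the calling module makes no attempt
to reproduce any proprietary platform's exact clustering defaults, only
the method class (k-means within dilution strata, tissue-anchored
labels); dilution factors are stratum labels, not physical quantities;
and the package computes genotype accuracy, not downstream parentage
assignment or relatedness.
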