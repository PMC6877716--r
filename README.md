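# ednasnp

Non-invasive SNP genotyping of aquatic animals from environmental DNA
(eDNA), for hatchery and selective-breeding workflows where tissue
sampling is harmful — e.g. bivalve broodstock that must be forced open to
clip mantle tissue. An animal is held in a small volume of clean
seawater, the DNA it sheds is recovered by filtration and genotyped on a
PCR-based platform, and the resulting calls are scored against tissue
references. Because eDNA template is dilute and degraded, single
reactions are unreliable; the package quantifies exactly how accuracy
depends on replication level, extraction method and dilution scheme.

## What it computes

For a bi-allelic SNP with genotype calls in {AA, AB, BB, NOCALL}:

* **Panel selection** — candidate SNPs ranked by mean minor allele
  frequency (MAF) across discovery populations; the top *k* form the
  assay panel (high MAF, conventionally > 0.2, discriminates best for
  parentage assignment).
* **Genotype calling** — per assay × dilution stratum, two-channel
  fluorescence intensities are min–max normalized, clustered by k-means
  (k chosen by average silhouette width), clusters labelled from the
  tissue reactions of the same dilution, and reactions beyond a no-call
  radius of every centroid set to NOCALL.
* **Call rate** — for a water sample with *R* replicate reactions across
  the panel, `call_rate = n_match / n_reactions`, counting every
  replicate independently and keeping NOCALLs in the denominator as
  non-matching.
* **Replication simulation** — for replication level *r*, draw *r* of
  the *n* available replicates per genotype without replacement, form
  the majority consensus excluding NOCALLs (ties and empty sets score
  incorrect), and compare to the tissue genotype. A Monte-Carlo
  estimator (100 scenarios by default) runs alongside the exact
  enumeration over all `choose(n, r)` subsets.
* **Synthetic study generator** — Hardy–Weinberg truth at the panel MAFs
  plus a per-scheme error model (no-call rate, miscall rate, cluster
  separation/noise), emulating the full 6-individual × 16-SNP ×
  8-dilution-scheme design so the pipeline runs end-to-end with no
  laboratory data.

## Worked example

```r
library(ednasnp)
cfg <- pipeline_config(out_dir = file.path(tempdir(), "demo"), seed = 1)
bundle <- run_pipeline(cfg)

bundle$call_rate_summary
#>    n mean_pct   sd_pct  min_pct max_pct
#> 1 48 68.71528 30.69439 2.083333     100

subset(bundle$simulation$summary, scheme_id %in% c("D2", "C1"))
#>    scheme_id replicate_level n_genotypes mean_accuracy exact_accuracy
#> 4         D2               1          96     0.9940625      0.9947917
#> 5         D2               2          96     0.9927083      0.9930556
#> 6         D2               3          96     1.0000000      1.0000000
#> 13        C1               1          96     0.9715625      0.9722222
#> 14        C1               2          96     0.9758333      0.9791667
#> 15        C1               3          96     0.9978125      0.9979167
```

Reading this: across the 48 synthetic water samples (6 individuals × 8
dilution schemes) the mean per-sample call rate is 68.7% with a wide
spread (2.1–100%) — dilution and extraction dominate success. The
best column-extraction scheme (D2) reaches 99.4% consensus accuracy from
a single replicate and 100% from three; the best crude-lysis scheme (C1)
reaches 97–100% depending on replication. `mean_accuracy` is the
100-scenario Monte-Carlo mean, `exact_accuracy` the closed-form
enumeration it estimates. The output directory also receives every
intermediate CSV, a YAML audit of the fitted cluster models, a log, and
a per-scenario accuracy figure.

Real platform exports enter the same pipeline through
`pipeline_config(input = "export.csv", ...)`; files that already carry
calls (no intensities) skip the calling stage automatically. A thin
command-line driver is installed at
`system.file("scripts", "edna_genotype.R", package = "ednasnp")`.

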