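# rohscan

Population-genomic analysis of multi-sample diploid SNP panels, centred on
**runs of homozygosity (ROH)**: contiguous chromosomal stretches where an
individual's genotypes are (nearly) all homozygous because both haplotypes
descend from a common ancestor. ROH are the standard genomic route to
inbreeding estimation in populations — such as indigenous livestock breeds —
where pedigrees are unavailable: the inbreeding coefficient is estimated as

```
F_ROH = (total ROH length in the individual) / (autosomal genome length)
```

and regions where ROH pile up across many individuals ("ROH islands") point
to selection or locally reduced diversity.

`rohscan` provides the full desk pipeline from a VCF to annotated islands:

- **Site filtering** — biallelic autosomal SNPs with MAF > 0.05, missing
  rate < 0.1, exact Hardy–Weinberg p > 1e-6 (Levene conditional test),
  site quality ≥ 20, with a reconciled per-criterion removal report.
- **Diversity statistics** — per-site MAF and nucleotide diversity
  π = n/(n−1)·(1 − Σᵢ xᵢ²) over non-missing allele copies, per-individual
  observed heterozygosity, and the GCTA genomic relationship matrix
  A_jk = (1/N)Σᵢ (x_ij − 2pᵢ)(x_ik − 2pᵢ)/(2pᵢ(1−pᵢ)) (Yang et al. 2010).
- **ROH detection** — a sliding window of 50 SNPs allowing ≤ 1 heterozygote
  and ≤ 5 missing calls; a SNP enters a run when ≥ 5% of its covering
  windows are homozygous; runs must hold ≥ 100 SNPs, span ≥ 500 kb, keep
  ≥ 1 SNP / 50 kb and contain no gap > 100 kb.
- **Summaries** — length classes (0.5–1, 1–2, 2–5, > 5 Mb), per-chromosome
  counts, per-individual F_ROH.
- **Islands and annotation** — per-SNP ROH incidence across individuals,
  islands where incidence exceeds 30% of samples, gene overlap from BED/GFF3.
- **Simulation** — seeded synthetic panels with HWE background genotypes and
  planted autozygous tracts with exported truth, so every stage is testable
  without external data.

Everything is tidyverse-native: functions take and return tibbles, results
chain with the pipe, and each result type has `autoplot()`/`tidy()`/
`glance()` methods.

## Worked example

```r
library(rohscan)

sim   <- simulate_panel(sim_preset_small(seed = 42))   # 10 ind x 20k SNPs
roh   <- detect_roh(sim$panel, roh_params())
f     <- froh(roh, sim$genome)
rec   <- evaluate_recovery(sim$truth, roh)

nrow(roh)
#> [1] 47
rec
#> <recovery_report> mean recall 0.9980, mean precision 0.9841, mean boundary error 17410 bp
head(f, 3)
#> # A tibble: 3 × 3
#>   individual total_roh_bp  f_roh
#>   <chr>             <dbl>  <dbl>
#> 1 ind01           2043532 0.0204
#> 2 ind02           3571734 0.0357
#> 3 ind03           5271875 0.0527
```

The preset plants autozygous tracts covering 2–16% of a 100 Mb two-
chromosome genome in 10 individuals. The detector recovers > 99% of planted
tract base pairs (recall), > 98% of detected base pairs lie inside planted
tracts (precision), and each individual's F_ROH lands within ~0.003 of its
planted autozygosity target. Islands follow from the same objects:

```r
track   <- snp_incidence(roh, sim$panel$sites)
islands <- call_islands(track, island_params())   # incidence > 0.30
```

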