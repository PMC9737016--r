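---
title: "Detecting runs of homozygosity: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting runs of homozygosity: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rohscan)
```

## The problem

In populations without pedigree records — indigenous livestock breeds are
the canonical case — inbreeding and recent demography must be read from the
genome itself. A run of homozygosity (ROH) is a contiguous stretch of a
chromosome where an individual's genotypes are (nearly) all homozygous,
which arises when both haplotypes descend from a common ancestor
(autozygosity). Long ROH indicate recent inbreeding, short ROH older
ancestry; the genomic inbreeding coefficient F_ROH is the fraction of the
autosomal genome lying inside ROH; and sites covered by ROH in a large
share of individuals ("islands") mark regions of shared homozygosity
consistent with selection.

`rohscan` implements the complete desk pipeline: VCF ingestion with
population-level site filters, per-site and per-individual diversity
statistics, a genomic relationship matrix, sliding-window ROH detection,
F_ROH and length-class summaries, island calling with gene annotation, and
a seeded simulator that validates the whole chain against planted truth.

## Site filtering

Sites are screened in a fixed order — autosome, site quality, missingness,
MAF, Hardy–Weinberg — and each removed site is attributed to its *first*
failing criterion, so removal counts always reconcile with the input count.
Defaults (all configurable in `filter_config()`):

| parameter | default | meaning |
|---|---|---|
| `maf_min` | 0.05 | minor allele frequency, strict `>` |
| `max_missing_rate` | 0.1 | missing genotype fraction, strict `<` |
| `hwe_p_min` | 1e-6 | exact-test p-value, strict `>` |
| `site_quality_min` | 20 | VCF QUAL, `>=`, only where recorded |
| `autosomes` | "1"–"29" | bovine autosome labels after `chr`-stripping |

The HWE screen is the exact conditional test: given the observed allele
counts, the heterozygote count follows the Levene distribution, and the
p-value sums the probability of every configuration no more probable than
the observed one (the Wigginton–Cutler–Abecasis convention used by standard
genotype-QC software). A chi-square variant is offered for very large
panels. Per-genotype read depth is upstream of the genotype-matrix
abstraction; a depth-based mask is deliberately not applied by default
because VCFs without FORMAT depth must remain first-class inputs.

Statistical imputation of missing genotypes is not performed: the window
scan budgets missing calls explicitly (below), which is the standard
fallback when an imputation step is skipped.

## Diversity statistics

Per site, with $n$ the number of non-missing allele copies and $x_i$ the
observed frequency of allele $i$:

$$\pi = \frac{n}{n-1}\Big(1 - \sum_i x_i^2\Big),$$

which is algebraically the mean difference over all $\binom{n}{2}$ pairs of
allele copies — the test suite checks the implementation against that
brute-force enumeration. Observed heterozygosity is reported per individual
as heterozygous calls over *called* genotypes (the called-SNP denominator;
with near-zero missingness the all-SNP denominator is indistinguishable,
and the column `n_called` makes the choice explicit).

Pairwise relatedness uses the GCTA estimator of Yang et al. (2010), with
allele frequencies taken from the analysed panel itself (the
within-population convention) and missing genotypes handled
pairwise-complete. Monomorphic sites carry no information and are excluded.

## The sliding-window ROH scan

Detection follows the three-stage window method (as in `detectRUNS` and
PLINK's `--homozyg`):

1. **Window classification.** A window of `window_size` (50) consecutive
   SNPs is *homozygous* when it contains at most `max_het_in_window` (1)
   heterozygous and at most `max_missing_in_window` (5) missing calls.
2. **SNP flagging.** Each SNP is covered by up to 50 windows; it is flagged
   when the proportion of covering windows that are homozygous is at least
   `window_pass_threshold` (0.05). "Minimum proportion of 0.05" is read as
   inclusive (`>=`).
3. **Run assembly and filtering.** Maximal stretches of consecutively
   flagged SNPs are split wherever adjacent flagged SNPs lie more than
   `max_gap_bp` (100 kb) apart, then filtered to runs with at least
   `min_snp_in_run` (100) SNPs, at least `min_length_bp` (500 kb,
   computed as `end − start + 1`), and density at least one SNP per
   `max_kb_per_snp` (50) kb.

Numerical and edge conventions, stated because they change output:

- **Chromosome ends.** Near an end a SNP has fewer than 50 covering
  windows. By default (`edge_mode = "shrink"`) the denominator shrinks to
  the number of windows that exist; `edge_mode = "skip"` keeps the full
  window count in the denominator, making edge SNPs proportionally harder
  to flag. Chromosomes with fewer SNPs than the window are scanned with a
  single truncated window.
- **Gap splitting** applies to consecutive *flagged* SNPs, not to raw SNP
  spacing inside windows.
- **Missing calls** inside a run occupy positions and count toward its SNP
  total, but never toward heterozygote counts — the window rule already
  budgets missingness.
- **Determinism.** The scan is pure arithmetic on the genotype vector;
  identical input yields byte-identical segment tables.

The optimized implementation (cumulative-sum window counts) is verified
against an exhaustive enumeration of every window and every
covering-window proportion on hundreds of random panels — exact equality,
not tolerance.

## Summaries, islands, annotation

Run lengths are binned into left-closed Mb classes `[0.5,1), [1,2), [2,5),
[5,∞)`; displayed percentages round half away from zero (so a 73.7/22.2/4.0
split prints as 74/22/4). F_ROH divides each individual's total run length
by the summed autosome lengths of a `genome_spec()`; because the published
convention leaves the denominator ambiguous, an alternative SNP-spanned
denominator (first to last SNP per chromosome) is also implemented —
`froh(..., denominator = "snp_span")`.

Per-SNP incidence counts the individuals whose runs cover each site; a SNP
is *significant* when incidence strictly exceeds `incidence_threshold`
(0.30 — with 30 individuals that means at least 10). Consecutive
significant SNPs at most `cluster_max_gap_bp` apart form one island. The
gap default (250 kb) is a package decision: published region tables do not
state how significant SNPs were clustered (adjacent reported regions
separated by tens of bp imply the original criterion was not purely
gap-based), so the incidence track is always exportable and the gap is a
parameter rather than a claim. Island boundaries are the outermost
significant SNPs, lengths are `end − start + 1` rounded half away from
zero to kb.

Gene annotation is a plain interval-overlap join (at least 1 bp, 1-based
inclusive coordinates) against gene-level records from BED or GFF3, with no
promoter or flank extension. Functional-enrichment statistics are out of
scope; the gene list is exported for any enrichment tool.

## The simulator: what it emulates, and what it does not

`simulate_panel()` generates the data structure the pipeline assumes:

- sites placed uniformly at random per chromosome, MAF drawn uniformly on
  `[0.05, 0.5]`, background genotypes Binomial(2, p) — i.e. exact HWE;
- autozygous tracts planted per individual, either explicitly or to hit a
  target genome fraction: inside a tract one allele is drawn per site with
  probability equal to the site frequency and doubled (two IBD copies of
  one draw — the population-genetic meaning of autozygosity), optionally
  flipped to a heterozygote with a configurable error rate;
- missingness applied last, uniformly at random.

The default genome is a synthetic 29-autosome set with linearly declining
lengths (158 to 51 Mb, roughly 2.5 Gb — bovine scale); the preset used for
validation, `sim_preset_small()`, is 10 individuals on two 50 Mb
chromosomes with 10,000 SNPs each (5 kb mean spacing) and per-individual
autozygosity targets spread over 0.02–0.16, mirroring the 1.6–16.7% F_ROH
range reported for low-inbreeding indigenous cattle. Tracts in the preset
are 1–5 Mb (≥ ~200 SNPs each) and placed with a 500 kb minimum separation
so distinct tracts remain distinct runs. These sizes keep the full
validation suite within seconds while every tract comfortably exceeds the
detector's 100-SNP/500-kb thresholds.

Deliberately **not** emulated: linkage disequilibrium between background
sites, allele-frequency spectra skewed by demography, non-uniform SNP
density, batch or depth-dependent genotyping error. Consequently, passing
the recovery tests demonstrates the detector's correctness and calibration
under its own model assumptions — it does not certify behaviour on real
data, where background LD produces chance homozygous stretches and can
inflate short-ROH counts.

## Validation results computed by the suite

With the preset above (seed 42), default detection parameters recover
planted tracts with mean base-pair recall ≥ 0.95 and precision ≥ 0.95, and
every individual's F_ROH lands within 0.02 of its planted target (observed:
recall ≈ 0.998, precision ≈ 0.984, max F_ROH error ≈ 0.003; boundary error
averages a few SNP spacings, since the flag spillover at tract edges is
limited to the handful of SNPs whose covering windows are mostly inside the
tract). The exact HWE test is checked against full enumeration for every
genotype table with up to 50 individuals.

## Known limitations

- The GRM with panel-estimated allele frequencies is not centred exactly at
  zero off-diagonal: the estimator satisfies
  $\overline{A}_{j \ne k} = -\overline{u^2}/(n-1) \approx -1/n$
  (about −0.02 at $n = 50$, −0.033 at $n = 30$), a finite-sample property
  of within-sample centering, not a bug; empirical cattle panels show the
  same slightly negative mean relatedness.
- Island clustering is gap-based by construction; where the original
  splitting of significant SNPs into regions used additional criteria, the
  island count will differ even when the significant-SNP set is identical.
- The window scan is the windowed method only; the window-free
  "consecutive runs" method is out of scope.
- `read_vcf()` targets biallelic SNPs with GT; multi-allelic records are
  dropped rather than decomposed.
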