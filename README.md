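# breedmap

Breed-structured mapping of canine compulsive-disorder loci.

Dog breeds are small, recently founded, genetically isolated populations.
That makes them powerful for mapping complex behavioural traits — a few
dozen cases within one breed can localize a risk haplotype — but the same
founding bottlenecks and artificial selection also drive risk alleles to
fixation, where case/control association is blind. A mapping study in this
setting therefore layers several analyses: within-breed GWAS, scans for
fixation and reduced variability, gene-set enrichment of candidate regions,
case-only variant burden from a small sequenced panel, and a breed-group
frequency contrast of candidate variants. `breedmap` implements that whole
workflow as composable, tidyverse-style R functions, together with a
breed-structured synthetic-data generator with planted ground truth so the
entire pipeline is testable end to end with no external data.

## The methods in brief

* **Genotype calling** from two-channel array intensities: pooled-target
  quantile normalization per chip, SNP-wise principal-component rotation,
  and EM clustering with a k = 3 bivariate t mixture (fixed ν = 5);
  component-to-genotype assignment is calibrated by genotype anchors
  estimated from the pooled cloud. Cohort QC: SNP call rate > 90%, sample
  call rate > 25%, MAF > 5%, in that order.
* **Association**: 1-df allelic chi-squared (no continuity correction),
  χ² = N(ad − bc)²⁄((a+b)(c+d)(a+c)(b+d)), then greedy LD clumping of
  signals (index P < 10⁻⁴; members within 1 Mb, dosage r² > 0.8,
  P < 0.01) and ±500 kb region→gene expansion.
* **Selection scans**: fixation regions (maximal intervals > 1,000 kb, more
  than 5 SNPs, > 95% of SNPs with MAF < 0.05) and regions of reduced
  variability (150 kb windows ranked by target-to-reference mean expected
  heterozygosity 2p(1−p), lowest 1% reported).
* **Enrichment**: interval-based permutation test — each candidate region
  is relocated at random preserving its length and overlapped-gene count,
  and a gene set's empirical P is (1 + #{null ≥ observed})⁄(1 + B), with
  min-P corrected P-values and an excess-of-nominally-significant-sets
  meta-P.
* **Case-only burden**: variants carried by ≥ 1 case and 0 controls (with a
  control call-rate requirement), restricted to constrained elements;
  per-dog counts compared by exact Wilcoxon rank-sum; per-gene burden in
  span ± 5 kb ranked by the (case-only + 1)/(control-only + 1) ratio;
  leave-one-breed-out reanalysis; six-criteria candidate selection.
* **Breed panel contrast**: normalized allele-frequency difference
  (AF_risk − AF_ctrl)/(AF_risk + AF_ctrl), group medians, paired Wilcoxon,
  and the Pearson correlation of overall frequency with the normalized
  difference.

## Worked example

```r
library(breedmap)

run <- run_pipeline(sim_config(seed = 42), n_perm = 2000)
run
#> <breedmap_run>
#>   caller concordance: 99.73% (call rate 92.4%)
#>   association regions (clumps): 5
#>   fixation regions: 1 | RRV windows: 4
#>   top enriched set: set018 empirical P = 0.694
#>   top burden gene: gene12 (12 case-only / 1 control-only constrained)
#>   panel contrast: median AF 0.189 vs 0.0526 | Pearson r = -0.573
```

Reading the output: the caller reproduced 99.73% of the planted genotypes
it called; association mapping collapsed the planted 5-SNP risk locus into
clump regions; the fixation scan found the planted 1.5 Mb near-monomorphic
interval (and not the 900 kb decoy); the reduced-variability scan reported
the lowest-1% windows including the planted zero-heterozygosity window; the
four planted burden genes occupy the top four burden ranks (ratios use a +1
pseudocount, raw counts reported alongside); and in the genotyping panel
the case-only variants are more common in risk breeds (median allele
frequency 0.189 versus 0.053), with the inverse frequency relationship
(r = −0.57) the planted rare-variant enrichment produces.

Each stage is also a standalone function returning a tibble
(`allelic_chisq()`, `clump()`, `fixation_scan()`, `rrv_scan()`,
`permutation_enrichment()`, `classify_variants()`, `gene_burden()`,
`frequency_contrast()`, ...), with broom-style `tidy()`/`glance()` methods
and `autoplot()` for association results, gene burdens, RRV scans and the
frequency contrast:

```r
glance(run$contrast)
#> # A tibble: 1 × 7
#>   median_risk median_ctrl wilcoxon_p pearson_r pearson_p n_variants n_excluded
#> 1       0.189      0.0526   7.70e-16    -0.573  2.63e-11        114          0

autoplot(run$assoc)     # Manhattan plot
autoplot(run$burden)    # case-only vs control-only per gene
autoplot(run$contrast)  # normalized AF difference vs overall AF
```

All simulated inputs can be written to disk as plain TSV/VCF/BED/GMT and
read back losslessly (`write_simulation()`, `read_vcf_geno()`,
`read_bed()`, `read_gmt()`, ...); identical seeds give byte-identical
files.

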