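---
title: "Mapping compulsive-disorder loci in dog breeds: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping compulsive-disorder loci in dog breeds: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(breedmap)
```

## The scientific problem

Canine compulsive disorder is a naturally occurring behavioural disease with
strongly elevated prevalence in a handful of breeds (Doberman Pinschers,
bull terriers, German shepherds). Because each breed is a recently founded,
genetically isolated population, risk alleles can be mapped with far smaller
cohorts than in humans — but the same bottlenecks that make mapping easier
also drive alleles to fixation, so a single analysis is not enough.
`breedmap` implements the complementary analyses such a study combines:

1. **Genotype calling from array intensities** — per-chip quantile
   normalization, SNP-wise principal components, EM clustering with a
   t-distribution mixture, and cohort QC.
2. **Within-breed case/control association** — allelic chi-squared tests,
   LD-based clumping of signals into candidate regions, and region→gene
   expansion.
3. **Selection scans** — breed fixation regions (long stretches of
   near-monomorphic SNPs) and regions of reduced variability (RRVs)
   relative to a reference breed panel, with breed-differential gene-set
   scoring.
4. **Interval-based permutation gene-set enrichment** of candidate regions.
5. **Case-only variant burden** from a small targeted-sequencing panel,
   restricted to evolutionarily constrained elements, with per-dog count
   comparisons and gene-level ratios.
6. **Breed-group frequency contrast** of candidate variants genotyped in an
   independent panel of high-risk and control breeds.

Every stage consumes and produces plain tables (tibbles) or small matrix
containers, and a synthetic-data generator produces all inputs with planted
ground truth so the entire pipeline is testable offline.

## The synthetic study and what it does (and does not) emulate

`sim_config()` fixes the study conditions. Allele frequencies follow the
Balding–Nichols model: each SNP draws an ancestral frequency $p$ uniformly
on $[0.05, 0.95]$ and each breed draws its frequency from
$\mathrm{Beta}\big(p\tfrac{1-F}{F},\,(1-p)\tfrac{1-F}{F}\big)$, so that
$\mathrm{Var} = F\,p(1-p)$. The default $F_{ST} = 0.2$ reflects the strong
differentiation of dog breeds; it is a single, analytically checkable knob
and is exposed in the config because no breed-panel-specific value is
canonical. Defaults are five breeds of 40 dogs (200 samples), 1,000 SNPs on
one 100 Mb chromosome; the first breed is the phenotyped target breed with
20 cases and 20 controls.

Planted truths define what the pipeline must recover:

* one association locus, realized as a cluster of five SNPs over 200 kb,
  each drawn at case frequency 0.85 versus control frequency 0.15 in the
  target breed. The effect is deliberately large: at 20 + 20 dogs an
  allelic test needs a non-centrality around 39 to clear the $P < 10^{-4}$
  clumping threshold reliably, which is the regime a within-breed study of
  a strongly associated haplotype operates in. The locus is multi-SNP
  because real associated haplotypes always are, and because per-SNP
  call-rate QC removes roughly a third of markers — a signal carried by one
  marker would vanish from the map in a large fraction of runs for reasons
  that have nothing to do with the association method;
* a 1.5 Mb fixed interval (all target-breed MAF ≤ 0.01), plus a 900 kb
  "decoy" that satisfies every fixation criterion except the 1 Mb span and
  must never be reported;
* one 150 kb window whose target-breed heterozygosity is erased;
* four genes carrying planted case-only/control-only variant burdens of
  16/2, 12/1, 10/3 and 16/2 — the case-only counts match the scale of the
  four top genes in the motivating study — placed inside constrained
  elements within gene span ± 5 kb;
* a genotyping panel of 114 variants in 69 risk-breed and 19 control-breed
  dogs, in which risk-breed frequencies are shifted up by 0.15 on variants
  rare in control breeds, producing both a median-frequency excess and the
  inverse relationship between overall frequency and the normalized
  frequency difference.

Planted intervals are guaranteed at least 10 SNPs (positions are re-gridded
if the uniform draw falls short) and their flanking SNPs are pinned to
frequency 0.5 in the target breed so the intervals have sharp, recoverable
edges; without the pins, neighbouring SNPs that drift to near-fixation by
chance would blur every interval boundary and make "the planted region"
ill-defined.

The generator does **not** model linkage disequilibrium decay, pedigree
structure, genotyping batch effects beyond a per-chip gain, or read-level
sequencing error. Passing tests therefore demonstrate that the *methods*
are implemented correctly and are well calibrated under a clean generative
model — not that they would be robust to LD confounding or cryptic
relatedness in real array data.

## Genotype calling

Two-channel intensities are emitted per sample and SNP as the cluster mean
of the true genotype plus independent t-distributed noise per channel
(scale = minimum inter-cluster distance / 6, $\nu = 5$; the heavy tails
stress the caller the way real array data do), multiplied by a per-chip
gain and floored at zero.

**Quantile normalization.** Each sample's pooled values (both channels, all
SNPs) are mapped to a reference quantile curve. The curve is built per chip
as the rank-mean curve of that chip's samples; chip curves are then
averaged after standardizing each to its mean level. With one chip this is
plain rank-mean quantile normalization (two samples `[1,2,3]` and
`[10,20,30]` both become `[5.5, 11, 16.5]`); with several chips the scale
standardization makes a per-chip gain collapse to a single global factor,
so calling is invariant to chip gain by construction. Within-sample rank
order is always preserved exactly.

**SNP-wise PCA and EM.** Each SNP's (A, B) cloud is centred and rotated to
its principal axes, PC1 oriented to increase with channel A. A k = 3
component bivariate t mixture (isotropic scale per component, fixed
$\nu = 5$) is fitted by EM using the normal/gamma augmentation, giving a
monotone log-likelihood; we cluster in both PC dimensions because the
second axis carries real information when clusters are noisy. Stopping is
at relative log-likelihood change $10^{-6}$, at most 200 iterations; the
cloud is standardized to unit RMS before fitting so the stopping rule is
scale-free. Calls are argmax-posterior genotypes, set missing below a 0.95
posterior threshold.

**Component→genotype assignment.** Per-SNP centring discards where the
cluster sits in absolute intensity space, so ordering components along PC1
cannot label a monomorphic SNP (one cluster at the origin can be AA or BB).
The pipeline therefore estimates three *genotype anchors* once, by k-means
on the pooled normalized cloud of all SNPs, ordered by A−B contrast, and
assigns each EM component the genotype of its nearest anchor in channel
space; components landing on the same anchor pool their posteriors. The
anchors also initialize the per-SNP EM (projected into PC space). We chose
anchor initialization over a quantile split along PC1 after observing that
the quantile split converges to a local optimum that splits the larger
homozygote cluster on SNPs with unbalanced genotype counts — roughly 17–20%
miscalls on such SNPs, versus 99.7% overall concordance with anchor starts.
The quantile split remains the default of the standalone
`em_t_mixture_call()`.

**Cohort QC** removes, in order: SNPs with call rate ≤ 90%, samples with
call rate ≤ 25%, and SNPs with MAF ≤ 5% (recomputed after sample removal).
The order matches the convention of standard GWAS toolkits; every removal
is reported with its reason.

## Association and clumping

The allelic test is the 1-df chi-squared on the 2×2 allele-by-status table
without continuity correction (the convention of PLINK's `--assoc`).
Clumping is greedy: the unassigned SNP with the smallest $P$ below
$10^{-4}$ indexes a clump that absorbs every unassigned SNP within 1 Mb
(index-to-member distance, inclusive — the source description does not say
whether 1 Mb bounds the distance or the total span; we chose the distance
reading and test against an oracle that encodes the same choice) with
dosage $r^2 > 0.8$ and $P < 0.01$. $r^2$ is the squared Pearson correlation
of dosages over pairwise-complete samples — a deterministic approximation
to haplotype-based LD. Regions expand by ±500 kb for gene mapping. A
validator re-checks disjointness and the member criteria on every run.

## Selection scans

**Fixation regions** are maximal SNP intervals spanning more than 1,000 kb,
containing more than five SNPs, with more than 95% of SNPs at within-breed
MAF < 0.05. Because the 95% fraction is not monotone under extension,
maximal intervals are found by exhaustive enumeration over index pairs
(prefix sums make this cheap), and correctness is pinned by a brute-force
oracle rather than by the scan's own cleverness. Overlapping maximal
intervals can exist; the report keeps the best-supported one per overlap
cluster (most SNPs, then highest low-MAF fraction, then leftmost) so that
regions are disjoint *and* each reported region itself satisfies the
printed criteria — merging overlapping intervals instead would produce
regions that fail the fraction rule, which the post-hoc validator would
reject.

**RRVs.** The genome is tiled in non-overlapping 150 kb windows; a window's
variability is its mean expected heterozygosity $2p(1-p)$ (the metric is
not specified by the source; expected heterozygosity is the field's default
diversity measure and is configurable), and the target breed's score is
divided by the mean reference-breed score plus $\varepsilon = 10^{-6}$ (so
reference-fixed windows do not produce infinite ratios). Exactly
$\lfloor 0.01 \times W \rfloor$ windows are reported. Score ties — typical
when several windows contain a single drifted SNP with zero sample
heterozygosity — are resolved in favour of windows with more SNPs, because
a ten-SNP zero-heterozygosity window is far stronger evidence of reduced
variability than one monomorphic SNP. For the same reason `rrv_scan()`
offers a `shrink` option — a pseudo-SNP at the genome-average
heterozygosity added to each window's target and reference means — which
the end-to-end pipeline enables (shrink = 1) when scanning *called*
genotypes: at ~1.5 SNPs per window, single drifted or miscalled monomorphic
SNPs otherwise produce exact-zero scores that outrank genuinely depleted
multi-SNP windows whose estimated heterozygosity is merely *near* zero.
The default (shrink = 0) is the plain mean-heterozygosity ratio. Whether
adjacent selected windows
merge into regions before counting is unknown for the original analysis;
merging is a flag (`merge_adjacent`), and the window count invariant is
defined pre-merge.

## Permutation enrichment

Gene sets with 5–1,000 mapped genes are tested. The observed statistic per
set is the number of regions containing at least one set gene; the null
relocates each region uniformly on the genome, preserving its length and
matching its overlapped-gene count within ±1 (a pool of matched placements
is pre-drawn per region). This preserves the confounders the interval
method is meant to control — region size, gene size and gene number —
without reproducing any specific external tool's matching scheme, which is
documented as a divergence. Empirical P-values use the add-one estimator
$(1 + \#\{\text{null} \ge \text{obs}\})/(1 + B)$, so they are never zero;
study-wide corrected P-values come from a min-P (Westfall–Young style)
second-level permutation, and the report counts sets below $P < 0.01$ with
a permutation meta-P for that excess (how the original study computed its
excess meta-P is not stated; a permutation count is our interpretation).

One numerical subtlety: with ~10 regions the overlap count takes few
values, so the add-one P is discrete with a large atom at 1 and cannot be
compared directly against a continuous uniform. The result therefore also
carries a *randomized* (uniformized) p-value — exactly uniform under the
null — used solely for calibration diagnostics; inference always uses the
conservative add-one estimator. Calibration checks also use exact
gene-count matching (`stratum_tol = 0`): in sparse gene landscapes where
windows overlap zero or one gene, the ±1 tolerance mixes the two strata
and biases the null upward for gene-desert regions.

## Case-only burden and the breed panel

A variant is **case-only** when its alternate allele is seen in at least
one case, in zero controls, and the genotype is non-missing in all controls
(the call-rate requirement is configurable; full call rate is the strict
default so missingness cannot masquerade as absence — the original analysis
does not state its requirement). Constrained-element membership uses
0-based half-open intervals. Per-dog counts of group-specific variants are
compared with a two-sided Wilcoxon rank-sum test: exact by enumeration with
midranks for groups of up to 10 dogs (count data always carry ties, which
would silently force `stats::wilcox.test` off its exact path), normal
approximation with tie correction above; `stats::wilcox.test` serves as the
cross-check on tie-free data.

Gene burden counts case-only and control-only variants in gene span ± 5 kb,
overall and within constrained elements, and ranks genes by the
pseudocounted ratio $(c+1)/(k+1)$ — the pseudocount lets genes with zero
control-only variants be ranked, and raw counts are always reported so the
unmodified ratio is recoverable. No multiple-testing correction is applied
to the per-gene ratios (they are descriptive, mirroring the original use);
a leave-one-breed-out reanalysis guards against the discovery breed driving
a gene's signal. Candidate selection for follow-up genotyping implements
the six panel-design criteria, with criteria i–iii restricted to
constrained elements.

The breed panel is QC'd (samples with > 10% missingness, then variants with
< 90% call rate) and summarized by the per-variant normalized frequency
difference $(a-b)/(a+b)$, group medians, a paired Wilcoxon signed-rank test
on the per-variant frequencies (the data are paired by variant; with an
all-zero difference vector the P-value is 1 by convention), and the Pearson
correlation between overall frequency and the normalized difference.

## Problem sizes and determinism

The default study — 200 samples × 1,000 SNPs for calling, 200-seed clumping
oracles, 100-seed burden recovery, 10,000-permutation enrichment — was
chosen so the full test suite and the end-to-end pipeline run comfortably
on a single CPU while leaving every planted signal in the regime where its
stage must detect it. All generators and permutation streams are seeded;
`simulate_study()` re-seeds from `config$seed`, and identical configs
produce byte-identical output files.

## Known limitations

* Genotype anchors assume all SNPs share one cluster geometry after
  normalization; real arrays have probe-specific cluster positions, which
  a production caller handles with per-SNP priors.
* Dosage $r^2$ understates haplotype LD when phase matters.
* The enrichment null relocates regions independently; clustered candidate
  regions on one chromosome arm are treated as exchangeable with the rest
  of the genome.
* The burden analysis treats consequence annotations as given and does not
  model sequencing error or mapping bias.
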