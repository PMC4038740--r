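#' Run the full mapping pipeline on a simulated study
#'
#' Chains every stage end to end on generated data: intensity simulation,
#' genotype calling, cohort QC, within-breed allelic association, LD
#' clumping with region expansion, fixation and reduced-variability scans,
#' permutation gene-set enrichment, case-only variant classification and
#' gene burden, per-dog count comparison, and the breed-panel frequency
#' contrast. Built-in validators (clump criteria, fixation criteria) are
#' re-checked on every run.
#'
#' Note the scans run on genotypes after call-rate QC only: the minor
#' allele frequency filter is an association-cohort filter and would remove
#' exactly the near-fixed SNPs the fixation scan is looking for.
#'
#' @param config a [sim_config()].
#' @param n_perm permutations for the enrichment stage.
#' @param rrv_quantile fraction of windows reported by the RRV scan.
#' @return A list of class `breedmap_run` with the intermediate results:
#'   `sim`, `calls`, `qc`, `concordance`, `assoc`, `clumps`,
#'   `region_genes`, `fixation`, `rrv`, `enrichment`, `variants` (classified
#'   table), `burden`, `dog_test`, `panel_qc`, `contrast`.
#' @export
run_pipeline <- function(config = sim_config(), n_perm = 2000,
                         rrv_quantile = 0.01) {
  cfg <- validate_sim_config(unclass(config))
  sim <- simulate_study(cfg)
  target <- breed_names(cfg)[1]

  calls <- call_genotypes(sim$intensities, sim$geno$samples,
                          df = cfg$intensity_model$df,
                          snp_map = sim$geno$snps)
  conc <- genotype_concordance(calls, sim$geno$truth)

  qc <- qc_filter(calls)
  scan_geno <- qc_filter(calls, min_maf = 0)$geno

  assoc_geno <- subset_geno(
    qc$geno, samples = qc$geno$samples$group %in% c("case", "control"))
  assoc <- allelic_chisq(assoc_geno)
  clumps <- clump(assoc, assoc_geno)
  validate_clumps(clumps, assoc)
  region_genes <- expand_regions(clumps, sim$genes, flank = 5e5)

  target_geno <- subset_geno(scan_geno,
                             samples = scan_geno$samples$breed == target)
  ref_geno <- subset_geno(scan_geno,
                          samples = scan_geno$samples$breed != target)
  fixation <- fixation_scan(target_geno)
  validate_fixed_regions(fixation, target_geno)
  # shrink = 1 pseudo-SNP: with ~1.5 SNPs per window and called (rather
  # than true) genotypes, the raw heterozygosity ratio is dominated by
  # single drifted or miscalled SNPs; support-weighted shrinkage keeps
  # well-populated low-variability windows on top
  rrv <- rrv_scan(target_geno, ref_geno, quantile = rrv_quantile,
                  chrom_length = cfg$chrom_length, shrink = 1)

  sets <- filter_sets(sim$gene_sets, sim$genes)
  enrichment <- if (nrow(clumps)) {
    permutation_enrichment(clumps, sets, sim$genes, n_perm = n_perm,
                           flank = 5e5,
                           chrom_lengths = tibble(chrom = cfg$chrom,
                                                  length = cfg$chrom_length))
  } else NULL

  vt <- classify_variants(sim$variants)
  vt <- intersect_constrained(vt, sim$constrained)
  burden <- gene_burden(vt, sim$genes)
  dog_test <- per_dog_count_test(vt, constrained_only = TRUE)

  pq <- genotyping_qc(sim$panel)
  contrast <- frequency_contrast(pq$panel)

  structure(
    list(sim = sim, calls = calls, qc = qc, concordance = conc,
         scan_geno = scan_geno,
         assoc = assoc, clumps = clumps, region_genes = region_genes,
         fixation = fixation, rrv = rrv, enrichment = enrichment,
         variants = vt, burden = burden, dog_test = dog_test,
         panel_qc = pq, contrast = contrast),
    class = "breedmap_run"
  )
}

#' @export
print.breedmap_run <- function(x, ...) {
  cat("<breedmap_run>\n")
  cat("  caller concordance:", sprintf("%.2f%%", 100 * x$concordance$concordance),
      sprintf("(call rate %.1f%%)\n", 100 * x$concordance$call_rate))
  cat("  association regions (clumps):", nrow(x$clumps), "\n")
  cat("  fixation regions:", nrow(x$fixation),
      "| RRV windows:", nrow(x$rrv$selected), "\n")
  if (!is.null(x$enrichment)) {
    cat("  top enriched set:", x$enrichment$sets$set[1],
        "empirical P =", signif(x$enrichment$sets$empirical_p[1], 3), "\n")
  }
  cat("  top burden gene:", x$burden$gene[1],
      sprintf("(%d case-only / %d control-only constrained)\n",
              x$burden$case_only_constrained[1],
              x$burden$control_only_constrained[1]))
  s <- x$contrast$summary
  cat("  panel contrast: median AF", signif(s$median_risk, 3), "vs",
      signif(s$median_ctrl, 3), "| Pearson r =", signif(s$pearson_r, 3), "\n")
  invisible(x)
}
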