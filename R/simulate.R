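#' Simulation configuration for a breed-structured mapping study
#'
#' Bundles every tunable of the synthetic-data generator: breed structure
#' (Balding-Nichols divergence), cohort layout, planted association loci,
#' planted fixed / reduced-variability regions, the two-channel intensity
#' model, and the targeted-sequencing / genotyping-panel design. Defaults
#' emulate a within-breed case/control array study of 200 dogs over one
#' 100 Mb chromosome with a strongly associated planted locus, one planted
#' 1.5 Mb fixed interval, a sub-threshold 900 kb near-fixed decoy, and one
#' 150 kb window of erased heterozygosity.
#'
#' @param n_breeds number of breeds; the first breed is the phenotyped
#'   target breed (cases and controls), the others are reference breeds.
#' @param n_per_breed samples per breed.
#' @param n_snps number of array SNPs on the simulated chromosome.
#' @param fst Balding-Nichols divergence parameter in (0, 1).
#' @param chrom,chrom_length chromosome name and length in bp.
#' @param case_fraction fraction of target-breed dogs labelled cases.
#' @param missing_rate genotype missingness rate injected into the coded
#'   genotype matrix (truth is retained separately).
#' @param planted_assoc tibble with columns `pos`, `f_case`, `f_control`:
#'   loci drawn at group-specific allele frequencies in the target breed.
#'   The default plants one associated locus as a cluster of five SNPs over
#'   200 kb — an associated haplotype is never a single marker, and a
#'   multi-SNP locus survives per-SNP call-rate attrition the way real
#'   signals do.
#' @param planted_fixed_region,planted_decoy_region lists
#'   `(start, end, max_maf)`: intervals where every target-breed SNP is
#'   forced to MAF below `max_maf`. The decoy's span is kept under the 1 Mb
#'   fixation-scan minimum so it must never be reported.
#' @param planted_rrv_region list `(start, end, het_scale)`: interval where
#'   target-breed expected heterozygosity is rescaled by `het_scale`
#'   (0 erases variability).
#' @param min_region_snps minimum number of SNPs guaranteed inside each
#'   planted interval (positions are re-gridded if the uniform draw falls
#'   short).
#' @param min_fixed_region_snps minimum SNPs inside the planted fixed
#'   interval; larger than `min_region_snps` so the interval keeps more
#'   than five SNPs even after cohort call-rate QC thins the map, while the
#'   decoy stays small enough that it can never satisfy the 95% low-MAF
#'   rule when extended past its own boundary.
#' @param boundary_snps,boundary_freq number of SNPs immediately flanking
#'   each planted interval that are pinned to `boundary_freq` in the target
#'   breed, giving planted intervals sharp edges.
#' @param intensity_model list with `means` (3 x 2 matrix of per-genotype
#'   two-channel cluster means, rows = genotypes 0/1/2), `noise_scale`
#'   (t-noise scale per channel; default = minimum inter-cluster distance
#'   divided by 6), `df` (t degrees of freedom) and `chip_factors` (named
#'   per-chip multiplicative scale factors).
#' @param seq_dogs tibble `dog`, `breed`, `group` describing the sequenced
#'   panel; default is 8 cases and 8 controls from four breeds (4+4, 2+2,
#'   1+1, 1+1).
#' @param n_genes,gene_length_range gene-catalog layout.
#' @param n_background_vars background (mostly shared) sequencing variants.
#' @param planted_burden_genes tibble `gene`, `n_case_only`,
#'   `n_control_only`: per-gene planted variant burdens.
#' @param constrained_fraction fraction of planted burden variants placed
#'   inside constrained elements.
#' @param background_constrained_rate probability a background variant
#'   falls in a constrained element.
#' @param n_panel_variants,n_risk_dogs,n_ctrl_dogs,panel_shift,rare_threshold,panel_missing_rate
#'   genotyping-panel design: number of case-only variants genotyped in an
#'   independent panel of risk-breed and control-breed dogs; risk-breed
#'   allele frequencies are shifted up by `panel_shift` on variants rarer
#'   than `rare_threshold` in control breeds.
#' @param seed integer seed used by [simulate_study()] and
#'   [write_simulation()] so identical configs give identical outputs.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_breeds = 5,
                       n_per_breed = 40,
                       n_snps = 1000,
                       fst = 0.2,
                       chrom = "chr1",
                       chrom_length = 100e6,
                       case_fraction = 0.5,
                       missing_rate = 0.01,
                       planted_assoc = tibble(pos = seq(45e6, 45.2e6, length.out = 5),
                                              f_case = 0.85, f_control = 0.15),
                       planted_fixed_region = list(start = 60e6, end = 61.5e6, max_maf = 0.01),
                       planted_decoy_region = list(start = 70e6, end = 70.9e6, max_maf = 0.01),
                       planted_rrv_region = list(start = 30e6, end = 30.15e6, het_scale = 0),
                       min_region_snps = 10,
                       min_fixed_region_snps = 24,
                       boundary_snps = 3,
                       boundary_freq = 0.5,
                       intensity_model = NULL,
                       seq_dogs = default_seq_dogs(),
                       n_genes = 60,
                       gene_length_range = c(20e3, 120e3),
                       n_background_vars = 300,
                       planted_burden_genes = tibble(
                         gene = c("gene05", "gene12", "gene21", "gene33"),
                         n_case_only = c(16L, 12L, 10L, 16L),
                         n_control_only = c(2L, 1L, 3L, 2L)
                       ),
                       constrained_fraction = 1.0,
                       background_constrained_rate = 0.05,
                       n_panel_variants = 114,
                       n_risk_dogs = 69,
                       n_ctrl_dogs = 19,
                       panel_shift = 0.15,
                       rare_threshold = 0.1,
                       panel_missing_rate = 0.02,
                       seed = 1L) {
  if (is.null(intensity_model)) {
    means <- rbind(`0` = c(2.0, 0.5), `1` = c(1.25, 1.25), `2` = c(0.5, 2.0))
    sep <- min(stats::dist(means))
    intensity_model <- list(means = means, noise_scale = sep / 6, df = 5,
                            chip_factors = c(chipA = 1.0, chipB = 1.15))
  }
  cfg <- list(
    n_breeds = n_breeds, n_per_breed = n_per_breed, n_snps = n_snps,
    fst = fst, chrom = chrom, chrom_length = chrom_length,
    case_fraction = case_fraction, missing_rate = missing_rate,
    planted_assoc = as_tibble(planted_assoc),
    planted_fixed_region = planted_fixed_region,
    planted_decoy_region = planted_decoy_region,
    planted_rrv_region = planted_rrv_region,
    min_region_snps = min_region_snps,
    min_fixed_region_snps = min_fixed_region_snps,
    boundary_snps = boundary_snps, boundary_freq = boundary_freq,
    intensity_model = intensity_model,
    seq_dogs = as_tibble(seq_dogs),
    n_genes = n_genes, gene_length_range = gene_length_range,
    n_background_vars = n_background_vars,
    planted_burden_genes = as_tibble(planted_burden_genes),
    constrained_fraction = constrained_fraction,
    background_constrained_rate = background_constrained_rate,
    n_panel_variants = n_panel_variants,
    n_risk_dogs = n_risk_dogs, n_ctrl_dogs = n_ctrl_dogs,
    panel_shift = panel_shift, rare_threshold = rare_threshold,
    panel_missing_rate = panel_missing_rate,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  counts <- c(cfg$n_breeds, cfg$n_per_breed, cfg$n_snps, cfg$n_genes)
  if (any(counts <= 0)) abort("all counts must be > 0", class = "breedmap_config_error")
  if (!(cfg$fst > 0 && cfg$fst < 1)) {
    abort("fst must lie in (0, 1)", class = "breedmap_config_error")
  }
  regions <- list(cfg$planted_fixed_region, cfg$planted_decoy_region,
                  cfg$planted_rrv_region)
  for (r in regions) {
    if (!is.null(r) &&
        !(r$start >= 0 && r$end > r$start && r$end <= cfg$chrom_length)) {
      abort("planted region coordinates must lie within [0, chrom_length)",
            class = "breedmap_config_error")
    }
  }
  if (nrow(cfg$planted_assoc) &&
      any(cfg$planted_assoc$pos < 0 | cfg$planted_assoc$pos >= cfg$chrom_length)) {
    abort("planted association positions must lie within [0, chrom_length)",
          class = "breedmap_config_error")
  }
  mu <- cfg$intensity_model$means
  if (min(stats::dist(mu)) <= 0) {
    abort("intensity cluster means must be pairwise distinct",
          class = "breedmap_config_error")
  }
  if (cfg$intensity_model$noise_scale < 0) {
    abort("noise scale must be >= 0", class = "breedmap_config_error")
  }
  structure(cfg, class = "sim_config")
}

#' Default sequenced-dog panel: 8 cases and 8 controls from four breeds
#' @return A tibble with columns `dog`, `breed`, `group`.
#' @export
default_seq_dogs <- function() {
  tibble(
    breed = c(rep("DP", 8), rep("GSD", 4), rep("JRT", 2), rep("SS", 2)),
    group = c(rep(c("case", "control"), c(4, 4)),
              rep(c("case", "control"), c(2, 2)),
              c("case", "control"), c("case", "control"))
  ) %>%
    group_by(.data$breed, .data$group) %>%
    mutate(dog = paste(.data$breed, .data$group, row_number(), sep = "_")) %>%
    ungroup() %>%
    select("dog", "breed", "group")
}

breed_names <- function(cfg) paste0("breed", seq_len(cfg$n_breeds))

# Rescale an allele frequency so expected heterozygosity 2p(1-p) is
# multiplied by s, staying on the same side of 1/2.
scale_het <- function(p, s) {
  h <- pmin(2 * p * (1 - p) * s, 0.5)
  lo <- (1 - sqrt(pmax(1 - 2 * h, 0))) / 2
  ifelse(p <= 0.5, lo, 1 - lo)
}

# Guarantee at least k SNP positions inside [start, end): the needed number
# of positions nearest the interval are moved onto an even grid inside it.
ensure_region_snps <- function(pos, start, end, k) {
  inside <- pos >= start & pos < end
  need <- k - sum(inside)
  if (need <= 0) return(sort(pos))
  centre <- (start + end) / 2
  movable <- which(!inside)
  need <- min(need, length(movable))
  if (need == 0) return(sort(pos))
  mv <- movable[order(abs(pos[movable] - centre))[seq_len(need)]]
  grid <- round(seq(start, end - 1, length.out = k))
  taken <- sort(pos[inside])
  # fill grid slots farthest from existing inside positions
  free <- grid
  if (length(taken)) {
    d <- vapply(grid, function(g) min(abs(g - taken)), numeric(1))
    free <- grid[order(-d)]
  }
  pos[mv] <- free[seq_len(need)]
  sort(pos)
}

#' Simulate per-breed allele frequencies under the Balding-Nichols model
#'
#' For each SNP an ancestral frequency p is drawn uniformly on
#' \[0.05, 0.95\] and each breed's frequency from
#' Beta(p(1-F)/F, (1-p)(1-F)/F) with F the divergence parameter, so that
#' Var(freq) = F p (1-p). Planted intervals then overwrite the target
#' breed's frequencies: fixed/decoy intervals are forced below their
#' `max_maf`, the reduced-variability interval has its heterozygosity
#' rescaled, and the SNPs flanking each planted interval are pinned common
#' so the intervals have sharp, recoverable edges.
#'
#' @param config a [sim_config()].
#' @return A tibble with columns `snp`, `chrom`, `pos`, `ancestral`,
#'   `breed`, `freq`, carrying a `truth` attribute that records the planted
#'   loci and intervals (association SNPs are snapped to the nearest
#'   simulated SNP).
#' @export
simulate_breed_frequencies <- function(config) {
  cfg <- validate_sim_config(unclass(config))
  pos <- sort(sample.int(cfg$chrom_length, cfg$n_snps) - 1L)
  fx <- cfg$planted_fixed_region
  if (!is.null(fx)) {
    pos <- ensure_region_snps(pos, fx$start, fx$end,
                              cfg$min_fixed_region_snps %||% cfg$min_region_snps)
  }
  for (r in list(cfg$planted_decoy_region, cfg$planted_rrv_region)) {
    if (!is.null(r)) pos <- ensure_region_snps(pos, r$start, r$end, cfg$min_region_snps)
  }
  pos <- sort(unique(pos))
  while (length(pos) < cfg$n_snps) {
    pos <- sort(unique(c(pos, sample.int(cfg$chrom_length, cfg$n_snps - length(pos)) - 1L)))
  }
  n <- length(pos)
  snp <- sprintf("snp%05d", seq_len(n))
  p_anc <- runif(n, 0.05, 0.95)
  brds <- breed_names(cfg)
  f <- cfg$fst
  freq <- matrix(NA_real_, n, cfg$n_breeds, dimnames = list(snp, brds))
  for (b in seq_len(cfg$n_breeds)) {
    if (f < 1e-9) {
      freq[, b] <- p_anc
    } else {
      freq[, b] <- rbeta(n, p_anc * (1 - f) / f, (1 - p_anc) * (1 - f) / f)
    }
  }

  target <- brds[1]
  pin <- function(region) {
    if (is.null(region)) return()
    inside <- which(pos >= region$start & pos < region$end)
    if (!is.null(region$max_maf)) {
      freq[inside, target] <<- runif(length(inside), 0, region$max_maf)
    } else {
      freq[inside, target] <<- scale_het(freq[inside, target], region$het_scale)
    }
    left <- which(pos < region$start)
    right <- which(pos >= region$end)
    flank <- c(tail(left, cfg$boundary_snps), head(right, cfg$boundary_snps))
    freq[flank, target] <<- cfg$boundary_freq
  }
  pin(cfg$planted_fixed_region)
  pin(cfg$planted_decoy_region)
  pin(cfg$planted_rrv_region)

  assoc <- cfg$planted_assoc
  if (nrow(assoc)) {
    # snap each planted locus to the nearest unused SNP
    idx <- integer(nrow(assoc))
    used <- rep(FALSE, n)
    for (i in seq_len(nrow(assoc))) {
      d <- abs(pos - assoc$pos[i])
      d[used] <- Inf
      idx[i] <- which.min(d)
      used[idx[i]] <- TRUE
    }
    assoc$snp <- snp[idx]
    assoc$pos <- pos[idx]
    assoc <- relocate(assoc, "snp")
    freq[idx, target] <- assoc$f_control
  }

  out <- tibble(
    snp = rep(snp, times = cfg$n_breeds),
    chrom = cfg$chrom,
    pos = rep(pos, times = cfg$n_breeds),
    ancestral = rep(p_anc, times = cfg$n_breeds),
    breed = rep(brds, each = n),
    freq = as.vector(freq)
  )
  attr(out, "truth") <- list(
    assoc = assoc,
    fixed_region = cfg$planted_fixed_region,
    decoy_region = cfg$planted_decoy_region,
    rrv_region = cfg$planted_rrv_region,
    target_breed = target
  )
  out
}

#' Simulate coded genotypes from per-breed allele frequencies
#'
#' Genotypes are Hardy-Weinberg draws within breed (allele-B dosage
#' Binomial(2, freq)). In the target breed, case/control labels are
#' assigned and planted association loci are drawn at the group-specific
#' frequencies recorded in the frequency table's truth attribute.
#' Missingness is injected at `config$missing_rate`; the complete matrix is
#' kept as `$truth` on the returned object.
#'
#' @param freqs output of [simulate_breed_frequencies()].
#' @param config a [sim_config()].
#' @return A [new_geno()] object with elements `truth` (complete genotype
#'   matrix) and a `truth` attribute carried over from `freqs`.
#' @export
simulate_genotypes <- function(freqs, config) {
  cfg <- validate_sim_config(unclass(config))
  if (any(freqs$freq < 0 | freqs$freq > 1)) {
    abort("allele frequencies must lie in [0, 1]")
  }
  truth <- attr(freqs, "truth")
  fr <- freqs %>%
    select("snp", "pos", "breed", "freq") %>%
    pivot_wider(names_from = "breed", values_from = "freq") %>%
    arrange(.data$pos)
  snp_ids <- fr$snp
  n_snps <- nrow(fr)
  brds <- breed_names(cfg)
  chips <- names(cfg$intensity_model$chip_factors)

  samples <- purrr::map(seq_along(brds), function(b) {
    k <- cfg$n_per_breed
    grp <- "unknown"
    if (b == 1) {
      n_case <- round(cfg$case_fraction * k)
      grp <- rep(c("case", "control"), c(n_case, k - n_case))
    }
    tibble(sample = sprintf("%s_s%03d", brds[b], seq_len(k)),
           breed = brds[b], group = grp)
  }) %>% list_rbind()
  samples$chip <- chips[(seq_len(nrow(samples)) - 1L) %% length(chips) + 1L]

  gt <- matrix(NA_integer_, nrow(samples), n_snps,
               dimnames = list(samples$sample, snp_ids))
  for (b in brds) {
    rows <- which(samples$breed == b)
    p <- fr[[b]]
    gt[rows, ] <- matrix(
      rbinom(length(rows) * n_snps, 2L, rep(p, each = length(rows))),
      nrow = length(rows)
    )
  }
  if (!is.null(truth) && nrow(truth$assoc)) {
    for (i in seq_len(nrow(truth$assoc))) {
      j <- match(truth$assoc$snp[i], snp_ids)
      for (g in c("case", "control")) {
        rows <- which(samples$group == g)
        fgrp <- if (g == "case") truth$assoc$f_case[i] else truth$assoc$f_control[i]
        gt[rows, j] <- rbinom(length(rows), 2L, fgrp)
      }
    }
  }
  complete <- gt
  if (cfg$missing_rate > 0) {
    gt[runif(length(gt)) < cfg$missing_rate] <- NA_integer_
  }
  g <- new_geno(gt, tibble(snp = snp_ids, chrom = cfg$chrom, pos = fr$pos,
                           ref = "A", alt = "B"),
                samples)
  g$truth <- complete
  attr(g, "truth") <- truth
  g
}

#' Simulate two-channel array intensities from true genotypes
#'
#' Each sample/SNP point is the cluster mean of its true genotype plus
#' independent t-distributed noise on each channel (scale
#' `noise_scale`, `df` degrees of freedom), multiplied by the sample's
#' chip scale factor. Intensities are floored at zero (detector floor).
#'
#' @param geno output of [simulate_genotypes()] (its `truth` matrix is
#'   used; missingness in the coded matrix does not propagate).
#' @param config a [sim_config()].
#' @return A tibble with columns `sample`, `chip`, `snp`, `a`, `b`.
#' @export
simulate_intensities <- function(geno, config) {
  cfg <- validate_sim_config(unclass(config))
  im <- cfg$intensity_model
  gt <- if (!is.null(geno$truth)) geno$truth else geno$gt
  if (anyNA(gt)) abort("true genotypes contain missing values")
  n <- length(gt)
  fac <- im$chip_factors[geno$samples$chip]
  noise_a <- if (im$noise_scale > 0) im$noise_scale * rt(n, im$df) else 0
  noise_b <- if (im$noise_scale > 0) im$noise_scale * rt(n, im$df) else 0
  a <- pmax(0, (im$means[gt + 1L, 1] + noise_a) * rep(fac, times = ncol(gt)))
  b <- pmax(0, (im$means[gt + 1L, 2] + noise_b) * rep(fac, times = ncol(gt)))
  tibble(
    sample = rep(rownames(gt), times = ncol(gt)),
    chip = rep(geno$samples$chip, times = ncol(gt)),
    snp = rep(colnames(gt), each = nrow(gt)),
    a = a, b = b
  )
}

#' Simulate a non-overlapping gene catalog
#'
#' Genes are placed on the chromosome with at least 12 kb between
#' neighbouring spans, so that 5 kb burden flanks never overlap.
#'
#' @param config a [sim_config()].
#' @return A tibble with columns `gene`, `chrom`, `start`, `end`
#'   (0-based half-open).
#' @export
simulate_gene_catalog <- function(config) {
  cfg <- validate_sim_config(unclass(config))
  n <- cfg$n_genes
  len <- round(runif(n, cfg$gene_length_range[1], cfg$gene_length_range[2]))
  gap_total <- cfg$chrom_length - sum(len)
  if (gap_total < 12e3 * (n + 1)) abort("chromosome too short for gene catalog")
  gaps <- as.vector(stats::rmultinom(1, gap_total - 12e3 * (n + 1),
                                     rep(1, n + 1))) + 12e3
  start <- cumsum(c(0, len[-n])) + cumsum(gaps[seq_len(n)])
  tibble(
    gene = sprintf("gene%02d", seq_len(n)),
    chrom = cfg$chrom,
    start = start,
    end = start + len
  )
}

#' Simulate constrained-element intervals
#'
#' Every gene receives 2-4 short elements inside its span; additional
#' elements are scattered in intergenic space. Coordinates are 0-based
#' half-open.
#'
#' @param config a [sim_config()].
#' @param gene_catalog output of [simulate_gene_catalog()].
#' @param n_intergenic number of intergenic elements.
#' @return A tibble with columns `chrom`, `start`, `end`, `element`.
#' @export
simulate_constrained_elements <- function(config, gene_catalog,
                                          n_intergenic = 100) {
  cfg <- validate_sim_config(unclass(config))
  genic <- purrr::pmap(gene_catalog, function(gene, chrom, start, end, ...) {
    k <- sample(2:4, 1)
    w <- round(runif(k, 200, 2000))
    s <- round(runif(k, start, pmax(start, end - w)))
    tibble(chrom = chrom, start = s, end = pmin(s + w, end))
  }) %>% list_rbind()
  w <- round(runif(n_intergenic, 200, 2000))
  s <- round(runif(n_intergenic, 0, cfg$chrom_length - w))
  out <- bind_rows(genic, tibble(chrom = cfg$chrom, start = s, end = s + w)) %>%
    arrange(.data$chrom, .data$start) %>%
    mutate(element = sprintf("ce%04d", row_number()))
  out
}

#' Simulate named gene sets
#'
#' Random sets of catalog genes, plus one "planted" set built from the
#' supplied gene ids (by default the planted burden genes), useful for
#' enrichment demonstrations.
#'
#' @param gene_catalog output of [simulate_gene_catalog()].
#' @param n_sets number of random sets.
#' @param size_range inclusive range of random set sizes.
#' @param planted_genes character vector for the planted set, or `NULL`.
#' @return A named list of character vectors of gene ids.
#' @export
simulate_gene_sets <- function(gene_catalog, n_sets = 30,
                               size_range = c(5, 40),
                               planted_genes = NULL) {
  sets <- lapply(seq_len(n_sets), function(i) {
    k <- sample(size_range[1]:min(size_range[2], nrow(gene_catalog)), 1)
    sort(sample(gene_catalog$gene, k))
  })
  names(sets) <- sprintf("set%03d", seq_len(n_sets))
  if (!is.null(planted_genes)) sets$planted_set <- sort(unique(planted_genes))
  sets
}

random_nonempty_subset <- function(ids, p = 0.4) {
  carriers <- ids[runif(length(ids)) < p]
  if (!length(carriers)) carriers <- sample(ids, 1)
  carriers
}

#' Simulate a targeted-sequencing variant table with planted gene burdens
#'
#' Background variants are placed uniformly outside the planted genes'
#' (span + 5 kb) windows with carriers drawn independently per dog, so
#' case-only and control-only background statuses arise only by chance.
#' For each planted gene the stated numbers of case-only and control-only
#' variants are placed inside the gene span +/- 5 kb, a
#' `constrained_fraction` of them inside constrained elements overlapping
#' that window.
#'
#' @param config a [sim_config()].
#' @param gene_catalog output of [simulate_gene_catalog()].
#' @param constrained output of [simulate_constrained_elements()].
#' @param flank flank in bp used to define the planted windows (matches the
#'   burden flank).
#' @return A `variant_table` object (see [new_variant_table()]) whose
#'   `truth` attribute records the planted per-gene counts and variant ids.
#' @export
simulate_variant_table <- function(config, gene_catalog, constrained,
                                   flank = 5000) {
  cfg <- validate_sim_config(unclass(config))
  planted <- cfg$planted_burden_genes
  missing_genes <- setdiff(planted$gene, gene_catalog$gene)
  if (length(missing_genes)) {
    abort(paste("planted burden genes not in catalog:",
                paste(missing_genes, collapse = ", ")),
          class = "breedmap_input_error")
  }
  dogs <- cfg$seq_dogs
  cases <- dogs$dog[dogs$group == "case"]
  ctrls <- dogs$dog[dogs$group == "control"]

  spans <- gene_catalog %>%
    filter(.data$gene %in% planted$gene) %>%
    mutate(wstart = pmax(0, .data$start - flank),
           wend = pmin(cfg$chrom_length, .data$end + flank))

  # background positions rejected out of planted windows
  bg_pos <- integer(0)
  while (length(bg_pos) < cfg$n_background_vars) {
    cand <- sample.int(cfg$chrom_length, cfg$n_background_vars) - 1L
    in_window <- rep(FALSE, length(cand))
    for (i in seq_len(nrow(spans))) {
      in_window <- in_window | (cand >= spans$wstart[i] & cand < spans$wend[i])
    }
    bg_pos <- unique(c(bg_pos, cand[!in_window]))
  }
  bg_pos <- sort(bg_pos[seq_len(cfg$n_background_vars)])

  bg_calls <- purrr::map(seq_along(bg_pos), function(i) {
    q <- runif(1, 0.05, 0.5)
    tibble(dog = dogs$dog, gt = rbinom(nrow(dogs), 2L, q))
  })

  plant_positions <- function(gene_row, k, constrained_k) {
    w <- spans[spans$gene == gene_row, ]
    ce <- constrained %>%
      filter(.data$start < w$wend, .data$end > w$wstart) %>%
      mutate(start = pmax(.data$start, w$wstart),
             end = pmin(.data$end, w$wend))
    pos_c <- integer(0)
    if (constrained_k > 0 && nrow(ce)) {
      el <- ce[sample.int(nrow(ce), constrained_k, replace = TRUE), ]
      pos_c <- as.integer(round(runif(constrained_k, el$start, el$end - 1)))
    }
    k_plain <- k - length(pos_c)
    pos_p <- integer(0)
    if (k_plain > 0) {
      pos_p <- as.integer(round(runif(k_plain, w$wstart, w$wend - 1)))
    }
    c(pos_c, pos_p)
  }

  planted_rows <- purrr::pmap(planted, function(gene, n_case_only, n_control_only) {
    k_c <- as.integer(round(cfg$constrained_fraction * n_case_only))
    k_k <- as.integer(round(cfg$constrained_fraction * n_control_only))
    pos_case <- plant_positions(gene, n_case_only, k_c)
    pos_ctrl <- plant_positions(gene, n_control_only, k_k)
    tibble(
      pos = c(pos_case, pos_ctrl),
      gene = gene,
      planted_status = rep(c("case-only", "control-only"),
                           c(n_case_only, n_control_only))
    )
  }) %>% list_rbind()

  planted_calls <- purrr::map(seq_len(nrow(planted_rows)), function(i) {
    carriers <- if (planted_rows$planted_status[i] == "case-only") {
      random_nonempty_subset(cases)
    } else {
      random_nonempty_subset(ctrls)
    }
    tibble(dog = dogs$dog,
           gt = if_else(dogs$dog %in% carriers, 1L, 0L))
  })

  variants <- bind_rows(
    tibble(pos = bg_pos, gene = NA_character_, planted_status = NA_character_),
    planted_rows
  ) %>%
    arrange(.data$pos) %>%
    mutate(
      variant_id = sprintf("var%05d", row_number()),
      chrom = cfg$chrom,
      ref = sample(c("A", "C", "G", "T"), n(), replace = TRUE),
      class = sample(c("SNP", "INDEL", "deletion"), n(), replace = TRUE,
                     prob = c(0.76, 0.235, 0.005)),
      consequence = sample(
        c("noncoding", "silent", "UTR", "missense", "splice", "nonsense",
          "frameshift"),
        n(), replace = TRUE,
        prob = c(0.90, 0.05, 0.02, 0.02, 0.005, 0.0025, 0.0025)
      )
    ) %>%
    mutate(alt = purrr::map_chr(.data$ref, function(r) {
      sample(setdiff(c("A", "C", "G", "T"), r), 1)
    }))

  calls_list <- c(bg_calls, planted_calls)[order(c(bg_pos, planted_rows$pos))]
  calls <- purrr::imap(calls_list, function(tb, i) {
    mutate(tb, variant_id = variants$variant_id[i])
  }) %>% list_rbind() %>%
    select("variant_id", "dog", "gt")

  vt <- new_variant_table(
    variants = select(variants, "variant_id", "chrom", "pos", "ref", "alt",
                      "class", "consequence"),
    calls = calls,
    dogs = dogs
  )
  attr(vt, "truth") <- list(
    planted = planted,
    planted_variants = variants %>%
      filter(!is.na(.data$gene)) %>%
      select("variant_id", "gene", "pos", "planted_status")
  )
  vt
}

#' Simulate a genotyping breed panel with planted frequency enrichment
#'
#' Emulates genotyping case-only variants in an independent panel of dogs
#' from high-risk breeds and control breeds. Control-breed allele
#' frequencies are drawn from a rare-skewed Beta; risk-breed frequencies
#' equal the control frequency plus `panel_shift` on variants rarer than
#' `rare_threshold`, producing both a median-frequency excess in risk
#' breeds and the inverse relationship between overall frequency and the
#' normalized frequency difference.
#'
#' @param config a [sim_config()].
#' @return A `breed_panel` object (see [new_breed_panel()]) with a `truth`
#'   attribute recording the generating frequencies.
#' @export
simulate_breed_panel <- function(config) {
  cfg <- validate_sim_config(unclass(config))
  m <- cfg$n_panel_variants
  af_ctrl <- rbeta(m, 0.6, 4)
  shift <- if_else(af_ctrl < cfg$rare_threshold, cfg$panel_shift,
                   cfg$panel_shift * 0.1)
  af_risk <- pmin(af_ctrl + shift, 0.98)
  dogs <- tibble(
    dog = c(sprintf("risk_%03d", seq_len(cfg$n_risk_dogs)),
            sprintf("ctrl_%03d", seq_len(cfg$n_ctrl_dogs))),
    breed_class = rep(c("risk", "control_breed"),
                      c(cfg$n_risk_dogs, cfg$n_ctrl_dogs))
  )
  gt <- matrix(NA_integer_, nrow(dogs), m,
               dimnames = list(dogs$dog, sprintf("pvar%04d", seq_len(m))))
  risk_rows <- which(dogs$breed_class == "risk")
  ctrl_rows <- which(dogs$breed_class == "control_breed")
  for (j in seq_len(m)) {
    gt[risk_rows, j] <- rbinom(length(risk_rows), 2L, af_risk[j])
    gt[ctrl_rows, j] <- rbinom(length(ctrl_rows), 2L, af_ctrl[j])
  }
  gt[runif(length(gt)) < cfg$panel_missing_rate] <- NA_integer_
  pos <- sort(sample.int(cfg$chrom_length, m) - 1L)
  panel <- new_breed_panel(
    gt = gt,
    variants = tibble(variant_id = colnames(gt), chrom = cfg$chrom, pos = pos),
    dogs = dogs
  )
  attr(panel, "truth") <- tibble(variant_id = colnames(gt),
                                 af_risk = af_risk, af_ctrl = af_ctrl)
  panel
}

#' Simulate the full study bundle
#'
#' Seeds the RNG from `config$seed` and generates every pipeline input:
#' breed frequencies, genotypes, intensities, gene catalog, constrained
#' elements, gene sets, the sequencing variant table, and the genotyping
#' breed panel, together with the planted-truth records.
#'
#' @param config a [sim_config()].
#' @return A list of class `breedmap_sim` with elements `config`, `freqs`,
#'   `geno`, `intensities`, `genes`, `constrained`, `gene_sets`,
#'   `variants`, `panel`, `truth`.
#' @export
simulate_study <- function(config = sim_config()) {
  cfg <- validate_sim_config(unclass(config))
  set.seed(cfg$seed)
  freqs <- simulate_breed_frequencies(cfg)
  geno <- simulate_genotypes(freqs, cfg)
  intens <- simulate_intensities(geno, cfg)
  genes <- simulate_gene_catalog(cfg)
  constrained <- simulate_constrained_elements(cfg, genes)
  gene_sets <- simulate_gene_sets(genes,
                                  planted_genes = cfg$planted_burden_genes$gene)
  variants <- simulate_variant_table(cfg, genes, constrained)
  panel <- simulate_breed_panel(cfg)
  truth <- c(attr(freqs, "truth"),
             list(burden = attr(variants, "truth"),
                  panel = attr(panel, "truth")))
  structure(
    list(config = cfg, freqs = freqs, geno = geno, intensities = intens,
         genes = genes, constrained = constrained, gene_sets = gene_sets,
         variants = variants, panel = panel, truth = truth),
    class = "breedmap_sim"
  )
}

#' @export
print.breedmap_sim <- function(x, ...) {
  cat("<breedmap_sim> seed", x$config$seed, "\n")
  cat(" ", nrow(x$geno$samples), "samples,", nrow(x$geno$snps), "SNPs,",
      nrow(x$genes), "genes,", nrow(x$variants$variants),
      "sequencing variants\n")
  invisible(x)
}
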