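test_that("configuration validation rejects invalid parameters", {
  expect_error(sim_config(fst = 0), class = "breedmap_config_error")
  expect_error(sim_config(fst = 1.2), class = "breedmap_config_error")
  expect_error(sim_config(n_snps = 0), class = "breedmap_config_error")
  expect_error(
    sim_config(planted_fixed_region = list(start = 99e6, end = 101e6,
                                           max_maf = 0.01)),
    class = "breedmap_config_error"
  )
  im <- sim_config()$intensity_model
  im$means[2, ] <- im$means[1, ]
  expect_error(sim_config(intensity_model = im),
               class = "breedmap_config_error")
})

test_that("breed frequencies follow the Balding-Nichols model", {
  set.seed(11)
  cfg <- sim_config(n_snps = 20000, fst = 0.2, planted_assoc = tibble::tibble(
    pos = numeric(), f_case = numeric(), f_control = numeric()))
  fr <- simulate_breed_frequencies(cfg)
  # variance of breed frequency around the ancestral value at p ~ 0.5 is
  # F p (1 - p) ~ 0.05 (exclude the target breed, which carries plants)
  mid <- dplyr::filter(fr, .data$ancestral > 0.45, .data$ancestral < 0.55,
                       .data$breed != "breed1")
  expect_gt(nrow(mid), 2000)
  v <- mean((mid$freq - mid$ancestral)^2)
  expect_lt(abs(v - 0.2 * 0.25), 0.008)

  # divergence limit: as F -> 0 breed frequencies collapse onto the ancestral
  set.seed(12)
  cfg0 <- sim_config(n_snps = 3000, fst = 1e-6,
                     planted_fixed_region = NULL,
                     planted_decoy_region = NULL,
                     planted_rrv_region = NULL,
                     planted_assoc = tibble::tibble(
                       pos = numeric(), f_case = numeric(),
                       f_control = numeric()))
  fr0 <- simulate_breed_frequencies(cfg0)
  expect_lt(max(abs(fr0$freq - fr0$ancestral)), 0.01)
})

test_that("planted intervals overwrite target-breed frequencies", {
  set.seed(13)
  cfg <- sim_config()
  fr <- simulate_breed_frequencies(cfg)
  tr <- attr(fr, "truth")
  target <- dplyr::filter(fr, .data$breed == "breed1")
  fx <- cfg$planted_fixed_region
  inside <- dplyr::filter(target, .data$pos >= fx$start, .data$pos < fx$end)
  expect_gte(nrow(inside), cfg$min_region_snps)
  expect_true(all(pmin(inside$freq, 1 - inside$freq) <= fx$max_maf))
  rv <- cfg$planted_rrv_region
  in_rrv <- dplyr::filter(target, .data$pos >= rv$start, .data$pos < rv$end)
  expect_true(all(2 * in_rrv$freq * (1 - in_rrv$freq) < 1e-12))
  expect_true(all(tr$assoc$snp %in% fr$snp))
})

test_that("genotypes are Hardy-Weinberg draws from the breed frequencies", {
  cfg <- sim_config(n_breeds = 2, n_per_breed = 500, n_snps = 40,
                    missing_rate = 0, planted_assoc = tibble::tibble(
                      pos = numeric(), f_case = numeric(),
                      f_control = numeric()))
  freqs <- tibble::tibble(
    snp = rep(sprintf("s%02d", 1:40), 2),
    chrom = "chr1",
    pos = rep(seq(0, by = 1e5, length.out = 40), 2),
    ancestral = 0.5,
    breed = rep(c("breed1", "breed2"), each = 40),
    freq = rep(c(0, 0.5), each = 20, times = 2)
  )
  set.seed(14)
  g <- simulate_genotypes(freqs, cfg)
  zero_snps <- freqs$snp[freqs$freq == 0][1:20]
  expect_true(all(g$gt[, zero_snps] == 0L))
  half <- g$gt[, setdiff(colnames(g$gt), zero_snps)]
  expect_lt(abs(mean(half == 1L) - 0.5), 0.02)  # HWE heterozygote share
  expect_lt(abs(mean(half) / 2 - 0.5), 0.02)
})

test_that("planted association locus is detectable at the designed power", {
  cfg <- sim_config(n_breeds = 1, n_per_breed = 400, n_snps = 30,
                    missing_rate = 0,
                    planted_fixed_region = NULL,
                    planted_decoy_region = NULL,
                    planted_rrv_region = NULL,
                    planted_assoc = tibble::tibble(pos = 1.5e6, f_case = 0.6,
                                                   f_control = 0.2),
                    chrom_length = 3e6)
  hits <- 0L
  set.seed(15)
  for (rep in 1:100) {
    fr <- simulate_breed_frequencies(cfg)
    g <- simulate_genotypes(fr, cfg)
    a <- allelic_chisq(g)
    planted_snp <- attr(fr, "truth")$assoc$snp
    hits <- hits + (a$p[a$snp == planted_snp] < 1e-4)
  }
  expect_gte(hits, 95)
})

test_that("intensity emission follows the cluster-mean + scaled-noise model", {
  cfg <- sim_config(n_breeds = 2, n_per_breed = 5, n_snps = 30)
  set.seed(16)
  fr <- simulate_breed_frequencies(cfg)
  g <- simulate_genotypes(fr, cfg)

  im0 <- cfg$intensity_model
  im0$noise_scale <- 0
  cfg0 <- sim_config(n_breeds = 2, n_per_breed = 5, n_snps = 30,
                     intensity_model = im0)
  ints <- simulate_intensities(g, cfg0)
  mu <- im0$means
  fac <- im0$chip_factors[g$samples$chip[match(ints$sample,
                                               g$samples$sample)]]
  truth_gt <- g$truth[cbind(match(ints$sample, rownames(g$truth)),
                            match(ints$snp, colnames(g$truth)))]
  expect_equal(ints$a, unname(mu[truth_gt + 1, 1] * fac))
  expect_equal(ints$b, unname(mu[truth_gt + 1, 2] * fac))

  # doubling one chip factor doubles exactly that chip's intensities
  im1 <- cfg$intensity_model
  im1$chip_factors <- c(chipA = 1, chipB = 1)
  im2 <- im1; im2$chip_factors <- c(chipA = 2, chipB = 1)
  cfg1 <- sim_config(n_breeds = 2, n_per_breed = 5, n_snps = 30,
                     intensity_model = im1)
  cfg2 <- sim_config(n_breeds = 2, n_per_breed = 5, n_snps = 30,
                     intensity_model = im2)
  set.seed(17); i1 <- simulate_intensities(g, cfg1)
  set.seed(17); i2 <- simulate_intensities(g, cfg2)
  on_a <- i1$chip == "chipA"
  expect_equal(i2$a[on_a], 2 * i1$a[on_a])
  expect_equal(i2$b[on_a], 2 * i1$b[on_a])
  expect_equal(i2$a[!on_a], i1$a[!on_a])
})

test_that("nearest-centroid classification is near-perfect at wide separation", {
  # per-channel cluster separation 6x the noise scale, near-Gaussian tails
  im <- list(means = rbind(c(2, 0.5), c(1.25, 1.25), c(0.5, 2)),
             noise_scale = 0.75 / 6, df = 200,
             chip_factors = c(c1 = 1))
  cfg <- sim_config(n_breeds = 2, n_per_breed = 100, n_snps = 100,
                    intensity_model = im, missing_rate = 0)
  set.seed(18)
  fr <- simulate_breed_frequencies(cfg)
  g <- simulate_genotypes(fr, cfg)
  ints <- simulate_intensities(g, cfg)
  d <- sapply(1:3, function(k) {
    (ints$a - im$means[k, 1])^2 + (ints$b - im$means[k, 2])^2
  })
  pred <- max.col(-d) - 1L
  truth_gt <- g$truth[cbind(match(ints$sample, rownames(g$truth)),
                            match(ints$snp, colnames(g$truth)))]
  expect_gte(mean(pred == truth_gt), 0.999)
})

test_that("variant table plants exact per-gene burdens and constrained placement", {
  set.seed(19)
  cfg <- sim_config()
  genes <- simulate_gene_catalog(cfg)
  ce <- simulate_constrained_elements(cfg, genes)
  vt <- simulate_variant_table(cfg, genes, ce)
  tr <- attr(vt, "truth")
  expect_setequal(unique(tr$planted_variants$gene), cfg$planted_burden_genes$gene)
  counts <- dplyr::count(tr$planted_variants, .data$gene, .data$planted_status)
  for (i in seq_len(nrow(cfg$planted_burden_genes))) {
    row <- cfg$planted_burden_genes[i, ]
    expect_equal(
      counts$n[counts$gene == row$gene & counts$planted_status == "case-only"],
      row$n_case_only
    )
    expect_equal(
      counts$n[counts$gene == row$gene &
                 counts$planted_status == "control-only"],
      row$n_control_only
    )
  }
  # constrained fraction 1: every planted variant inside an element
  vt2 <- intersect_constrained(vt, ce)
  planted_flag <- vt2$variants$constrained[
    match(tr$planted_variants$variant_id, vt2$variants$variant_id)]
  expect_true(all(planted_flag))
  # unknown planted gene is an input error
  bad <- cfg
  bad$planted_burden_genes$gene[1] <- "nonexistent"
  expect_error(simulate_variant_table(bad, genes, ce),
               class = "breedmap_input_error")
})

test_that("without planted burdens, group-specific counts are exchangeable", {
  set.seed(20)
  cfg <- sim_config(planted_burden_genes = tibble::tibble(
    gene = character(), n_case_only = integer(), n_control_only = integer()))
  genes <- simulate_gene_catalog(cfg)
  ce <- simulate_constrained_elements(cfg, genes)
  vt <- simulate_variant_table(cfg, genes, ce)
  vt <- classify_variants(vt)
  b <- gene_burden(vt, genes)
  more_case <- sum(b$case_only > b$control_only)
  informative <- sum(b$case_only != b$control_only)
  if (informative > 0) {
    p <- stats::binom.test(more_case, informative)$p.value
    expect_gt(p, 0.05)
  }
  expect_lt(max(b$case_only), 5)
})

test_that("identical seed and config give byte-identical output files", {
  cfg <- sim_config(n_snps = 120, n_per_breed = 6, n_breeds = 3,
                    n_genes = 20, n_background_vars = 60,
                    planted_burden_genes = tibble::tibble(
                      gene = c("gene05", "gene12"),
                      n_case_only = c(6L, 4L), n_control_only = c(1L, 2L)),
                    seed = 77)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_simulation(simulate_study(cfg), d1)
  write_simulation(simulate_study(cfg), d2)
  f1 <- sort(list.files(d1))
  expect_identical(f1, sort(list.files(d2)))
  for (f in f1) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = paste("checksum of", f))
  }
})
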