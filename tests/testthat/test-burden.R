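test_that("variant classification follows the carrier and call-rate rules", {
  vt <- make_variant_table(
    positions = c(100, 200, 300, 400, 500),
    carriers = list(
      c("case1", "case2", "case3"),   # case-only
      c("case1", "ctrl1"),            # shared
      c("ctrl2"),                     # control-only
      character(0),                   # alt in nobody -> shared
      c("case4")                      # case-only, but see missingness below
    )
  )
  # variant 5: one control genotype missing -> private-missing at full
  # call-rate requirement
  vt$calls$gt[vt$calls$variant_id == "v005" & vt$calls$dog == "ctrl3"] <- NA
  out <- classify_variants(vt, control_callrate_min = 1)
  st <- out$variants$status[match(paste0("v00", 1:5), out$variants$variant_id)]
  expect_equal(st, c("case-only", "shared", "control-only", "shared",
                     "private-missing"))
  # relaxing the call-rate requirement promotes variant 5 to case-only
  out2 <- classify_variants(vt, control_callrate_min = 0.7)
  expect_equal(out2$variants$status[out2$variants$variant_id == "v005"],
               "case-only")
  # status is a partition
  expect_equal(sum(table(out$variants$status)), nrow(out$variants))

  # a variant missing in every dog is excluded with a message
  vt$calls$gt[vt$calls$variant_id == "v004"] <- NA
  expect_message(out3 <- classify_variants(vt), "excluded")
  expect_false("v004" %in% out3$variants$variant_id)
})

test_that("constrained-element intersection is half-open and matches brute force", {
  elements <- tibble::tibble(chrom = "chr1",
                             start = c(1000, 5000), end = c(2000, 5100))
  vt <- make_variant_table(
    positions = c(1000, 1999, 2000, 5099, 5100),
    carriers = replicate(5, "case1", simplify = FALSE)
  )
  out <- intersect_constrained(vt, elements)
  expect_equal(out$variants$constrained, c(TRUE, TRUE, FALSE, TRUE, FALSE))

  set.seed(61)
  for (rep in 1:20) {
    ne <- sample(1:10, 1)
    es <- sort(sample(1:1e6, ne))
    elements <- tibble::tibble(chrom = "chr1", start = es,
                               end = es + sample(10:5000, ne, replace = TRUE))
    pos <- sample(1:1.1e6, 50)
    vt <- make_variant_table(pos, replicate(50, "case1", simplify = FALSE))
    got <- intersect_constrained(vt, elements)$variants$constrained
    expect_identical(got,
                     oracle_in_intervals(pos, elements$start, elements$end))
  }
})

test_that("per-dog count test reproduces the exact rank-sum distribution", {
  # identical count vectors -> P = 1
  expect_equal(breedmap:::rank_sum_test(c(3, 3), c(3, 3))$p, 1)
  # hand case: [15,15,16,14] vs [4,3,4,5] -> all case ranks above control;
  # exact two-sided P = 2/70
  got <- breedmap:::rank_sum_test(c(15, 15, 16, 14), c(4, 3, 4, 5))
  expect_equal(got$p, 2 / 70, tolerance = 1e-12)
  expect_equal(got$method, "exact")
  # tie-free data agree with stats::wilcox.test's exact distribution
  set.seed(62)
  for (rep in 1:20) {
    x <- sample(seq(1, 3999, by = 2), 6)   # odd values
    y <- sample(seq(2, 4000, by = 2), 5)   # even values: no ties possible
    ref <- stats::wilcox.test(x, y, exact = TRUE)$p.value
    expect_equal(breedmap:::rank_sum_test(x, y)$p, ref, tolerance = 1e-10)
  }
  # large groups switch to the tie-corrected normal approximation
  set.seed(63)
  x <- rpois(15, 10); y <- rpois(15, 12)
  got <- breedmap:::rank_sum_test(x, y)
  ref <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                             correct = FALSE))$p.value
  expect_equal(got$method, "normal")
  expect_equal(got$p, ref, tolerance = 1e-9)
})

test_that("per-dog counts honor restriction flags and exclusions", {
  # 4 case dogs carrying many case-only variants, controls carrying few
  positions <- c(seq(100, by = 10, length.out = 12), 500, 600, 700)
  carriers <- c(
    lapply(1:12, function(i) paste0("case", (i %% 4) + 1)),
    list("ctrl1", "ctrl2", c("ctrl3", "case1"))
  )
  vt <- make_variant_table(positions, carriers,
                           consequence = c(rep("noncoding", 10),
                                           rep("missense", 2),
                                           rep("noncoding", 3)))
  vt <- classify_variants(vt)
  vt <- intersect_constrained(vt, tibble::tibble(chrom = "chr1", start = 0,
                                                 end = 250))
  res <- per_dog_count_test(vt)
  expect_equal(nrow(res$counts), 8)
  expect_equal(sum(res$counts$n[res$counts$group == "case"]), 12)
  expect_equal(sum(res$counts$n[res$counts$group == "control"]), 2)
  expect_lt(res$test$p, 0.05)

  # constrained_only keeps only variants below position 250
  res_c <- per_dog_count_test(vt, constrained_only = TRUE)
  expect_equal(sum(res_c$counts$n), 12)
  # excluding coding variants removes the two missense case-only variants
  res_nc <- per_dog_count_test(vt, exclude_coding = TRUE)
  expect_equal(sum(res_nc$counts$n[res_nc$counts$group == "case"]), 10)
  # dog exclusions are honored and group minimums enforced
  res_ex <- per_dog_count_test(vt, exclude = c("case1"))
  expect_equal(nrow(res_ex$counts), 7)
  expect_error(per_dog_count_test(vt, exclude = paste0("ctrl", 1:3)),
               "at least 2")
})

test_that("gene burden counts variants in flanked spans with the pseudocount ratio", {
  genes <- tibble::tibble(gene = c("gA", "gB"), chrom = "chr1",
                          start = c(10000, 50000), end = c(20000, 60000))
  # 16 case-only + 2 control-only in gA +/- 5 kb (some in the flanks),
  # nothing in gB
  pos_case <- c(round(seq(5000, 24999, length.out = 15)), 10000)
  pos_ctrl <- c(7000, 24000)
  positions <- c(pos_case, pos_ctrl, 40000)  # last one between genes
  carriers <- c(lapply(1:16, function(i) paste0("case", (i %% 4) + 1)),
                list("ctrl1", "ctrl2", "case1"))
  vt <- make_variant_table(positions, carriers)
  vt <- classify_variants(vt)
  vt <- intersect_constrained(vt, tibble::tibble(chrom = "chr1", start = 0,
                                                 end = 1e6))
  b <- gene_burden(vt, genes, flank = 5000)
  gA <- b[b$gene == "gA", ]
  expect_equal(gA$case_only, 16)
  expect_equal(gA$control_only, 2)
  expect_equal(gA$ratio, 17 / 3, tolerance = 1e-12)
  gB <- b[b$gene == "gB", ]
  expect_equal(gB$case_only, 0)
  expect_equal(gB$ratio, 1)
  expect_equal(b$gene[b$rank == 1], "gA")

  # burden counts are monotone in the flank
  b0 <- gene_burden(vt, genes, flank = 0)
  expect_true(all(b0$case_only[match(b$gene, b0$gene)] <= b$case_only))
  expect_true(all(b0$control_only[match(b$gene, b0$gene)] <= b$control_only))
  expect_equal(b0$case_only[b0$gene == "gA"], 8)  # flank variants drop out
})

test_that("planted burden genes are recovered as the top-ranked genes", {
  set.seed(64)
  cfg <- sim_config()
  genes <- simulate_gene_catalog(cfg)
  ce <- simulate_constrained_elements(cfg, genes)
  vt <- simulate_variant_table(cfg, genes, ce)
  vt <- classify_variants(vt)
  vt <- intersect_constrained(vt, ce)
  b <- gene_burden(vt, genes)
  top4 <- b$gene[b$rank <= 4]
  expect_setequal(top4, cfg$planted_burden_genes$gene)
  # classified counts equal the truth sidecar exactly
  tr <- attr(vt, "truth")
  for (i in seq_len(nrow(cfg$planted_burden_genes))) {
    row <- cfg$planted_burden_genes[i, ]
    expect_equal(b$case_only[b$gene == row$gene], row$n_case_only)
    expect_equal(b$control_only[b$gene == row$gene], row$n_control_only)
  }
})

test_that("leave-breed-out equals classification on the manually subsetted table", {
  set.seed(65)
  cfg <- sim_config()
  genes <- simulate_gene_catalog(cfg)
  ce <- simulate_constrained_elements(cfg, genes)
  vt <- simulate_variant_table(cfg, genes, ce)
  lbo <- leave_breed_out(vt, "GSD", genes, constrained = ce)
  keep <- vt$dogs$dog[vt$dogs$breed != "GSD"]
  manual <- subset_dogs(vt, keep)
  manual <- classify_variants(manual)
  manual <- intersect_constrained(manual, ce)
  manual_b <- gene_burden(manual, genes)
  expect_equal(lbo, manual_b)

  # removing a breed with no carriers leaves the burden unchanged
  vt_extra <- vt
  vt_extra$dogs <- dplyr::bind_rows(
    vt_extra$dogs,
    tibble::tibble(dog = "lurker", breed = "Whippet", group = "control"))
  vt_extra$calls <- dplyr::bind_rows(
    vt_extra$calls,
    tibble::tibble(variant_id = vt$variants$variant_id, dog = "lurker",
                   gt = 0L))
  base <- gene_burden(
    intersect_constrained(classify_variants(vt), ce), genes)
  lbo2 <- leave_breed_out(vt_extra, "Whippet", genes, constrained = ce)
  expect_equal(lbo2, base)

  # removing a breed that empties a group is an error
  vt_small <- make_variant_table(
    c(100, 200), list("case1", "ctrl1"),
    dogs = tibble::tibble(dog = c("case1", "case2", "ctrl1", "ctrl2"),
                          breed = c("A", "A", "B", "B"),
                          group = c("case", "case", "control", "control")))
  expect_error(leave_breed_out(vt_small, "A", tibble::tibble(
    gene = "g", chrom = "chr1", start = 0, end = 1000)), "empties")
})

test_that("candidate selection applies the six panel-design criteria", {
  genes <- tibble::tibble(gene = c("burden1", "other"), chrom = "chr1",
                          start = c(10000, 100000), end = c(20000, 110000))
  dogs <- tibble::tibble(
    dog = c("dp_case", "gs_case", "jr_case", "dp_ctrl", "gs_ctrl", "jr_ctrl"),
    breed = c("DP", "GSD", "JRT", "DP", "GSD", "JRT"),
    group = rep(c("case", "control"), each = 3)
  )
  positions <- c(30000, 15000, 40000, 50000, 70000, 80000, 90000)
  carriers <- list(
    "dp_case",                 # (i) DP case-only, constrained
    "gs_case",                 # (ii) in burden1 span, constrained
    c("dp_case", "gs_case"),   # (iii) case-only in two breeds, constrained
    "jr_case",                 # (iv) missense case-only (not constrained)
    "dp_ctrl",                 # (v) inside risk haplotype (any status)
    "gs_case",                 # (vi) at a top GWAS position (constrained)
    "jr_ctrl"                  # control-only, qualifies nowhere
  )
  consequence <- c("noncoding", "noncoding", "noncoding", "missense",
                   "noncoding", "noncoding", "noncoding")
  vt <- make_variant_table(positions, carriers, consequence = consequence,
                           dogs = dogs)
  vt <- classify_variants(vt)
  # constrained everywhere except the missense variant and the risk-region one
  vt <- intersect_constrained(vt, tibble::tibble(
    chrom = "chr1", start = c(0, 75000), end = c(45000, 95000)))
  assoc <- tibble::tibble(chrom = "chr1", pos = 80000, p = 1e-6)
  cand <- select_candidates(
    vt, genes, burden_genes = "burden1", target_breed = "DP",
    assoc = assoc, risk_region = list(chrom = "chr1", start = 65000,
                                      end = 72000)
  )
  expect_equal(nrow(cand), 6)
  crit <- setNames(cand$criteria, cand$variant_id)
  expect_true(grepl("i", crit[["v001"]]))
  expect_true(grepl("ii", crit[["v002"]]))
  expect_true(grepl("iii", crit[["v003"]]))
  expect_equal(crit[["v004"]], "iv")
  expect_equal(crit[["v005"]], "v")
  expect_true(grepl("vi", crit[["v006"]]))
  expect_false("v007" %in% cand$variant_id)
  # the DP case-only constrained variant also satisfies nothing else
  expect_equal(crit[["v001"]], "i")
  expect_error(
    select_candidates(vt, genes, burden_genes = "no_such_gene"),
    "unknown gene"
  )
})

test_that("genotyping QC filters samples then variants at the printed thresholds", {
  set.seed(66)
  gt <- matrix(rbinom(20 * 10, 2, 0.3), 20, 10)
  dogs <- tibble::tibble(dog = sprintf("d%02d", 1:20),
                         breed_class = rep(c("risk", "control_breed"),
                                           c(15, 5)))
  variants <- tibble::tibble(variant_id = sprintf("pv%02d", 1:10),
                             chrom = "chr1", pos = (1:10) * 1000)
  rownames(gt) <- dogs$dog; colnames(gt) <- variants$variant_id
  gt[1, 1:2] <- NA      # dog 1: missing 2/10 = 20% > 10% -> removed
  gt[2, 1] <- NA        # dog 2: 10% missing -> kept (not strictly greater)
  gt[3:8, 3] <- NA      # variant 3 call rate: depends on dog removals
  panel <- new_breed_panel(gt, variants, dogs)
  res <- genotyping_qc(panel)
  expect_true("d01" %in% res$report$id)
  expect_false("d02" %in% res$report$id)
  # after removing d01: variant 3 has 6 missing of 19 -> 68% < 90% -> removed
  expect_true("pv03" %in% res$report$id)
  # variant at exactly 90%: kept (not strictly lower than 90%)
  expect_false("pv01" %in% res$report$id[res$report$entity == "variant"])
  # sample step precedes variant step
  steps <- res$report$step[match(c("d01", "pv03"), res$report$id)]
  expect_true(steps[1] < steps[2])
  survivors_manual <- setdiff(dogs$dog, "d01")
  expect_setequal(rownames(res$panel$gt), survivors_manual)
})

test_that("normalized AF difference is antisymmetric, bounded and exact", {
  expect_equal(normalized_af_diff(0.17, 0.05), 0.12 / 0.22, tolerance = 1e-13)
  expect_equal(normalized_af_diff(0.2, 0), 1)
  expect_equal(normalized_af_diff(0, 0.2), -1)
  for (x in c(0.01, 0.3, 0.99)) expect_equal(normalized_af_diff(x, x), 0)
  set.seed(67)
  a <- runif(50); b <- runif(50)
  expect_equal(normalized_af_diff(a, b), -normalized_af_diff(b, a))
  expect_true(all(abs(normalized_af_diff(a, b)) <= 1))
  expect_true(is.na(normalized_af_diff(0, 0)))
  expect_error(normalized_af_diff(1.2, 0.5), class = "breedmap_input_error")
})

test_that("frequency contrast matches hand computation on a 5-variant table", {
  # risk group: 2 dogs; control group: 2 dogs
  gt <- rbind(
    r1 = c(2L, 1L, 0L, 1L, 2L),
    r2 = c(1L, 1L, 0L, 0L, 2L),
    c1 = c(0L, 1L, 2L, 0L, 2L),
    c2 = c(1L, 0L, 2L, 0L, 2L)
  )
  dogs <- tibble::tibble(dog = c("r1", "r2", "c1", "c2"),
                         breed_class = c("risk", "risk", "control_breed",
                                         "control_breed"))
  variants <- tibble::tibble(variant_id = paste0("v", 1:5), chrom = "chr1",
                             pos = 1:5 * 100)
  colnames(gt) <- variants$variant_id
  panel <- new_breed_panel(gt, variants, dogs)
  fc <- frequency_contrast(panel)
  af_risk <- c(3, 2, 0, 1, 4) / 4
  af_ctrl <- c(1, 1, 4, 0, 4) / 4
  expect_equal(fc$variants$af_risk, af_risk)
  expect_equal(fc$variants$af_ctrl, af_ctrl)
  expect_equal(fc$variants$af_all, (af_risk + af_ctrl) / 2)
  expect_equal(fc$variants$norm_diff,
               (af_risk - af_ctrl) / (af_risk + af_ctrl))
  expect_equal(fc$summary$median_risk, median(af_risk))
  expect_equal(fc$summary$median_ctrl, median(af_ctrl))
  ct <- cor.test((af_risk + af_ctrl) / 2,
                 (af_risk - af_ctrl) / (af_risk + af_ctrl))
  expect_equal(fc$summary$pearson_r, unname(ct$estimate))
  expect_equal(fc$summary$pearson_p, ct$p.value)

  # identical group frequencies: all diffs zero, P = 1
  gt2 <- rbind(r1 = c(2L, 0L, 1L), r2 = c(0L, 2L, 1L),
               c1 = c(2L, 0L, 1L), c2 = c(0L, 2L, 1L))
  colnames(gt2) <- paste0("w", 1:3)
  panel2 <- new_breed_panel(
    gt2, tibble::tibble(variant_id = paste0("w", 1:3), chrom = "chr1",
                        pos = 1:3), dogs)
  expect_warning(fc2 <- frequency_contrast(panel2, min_variants = 3),
                 "degenerate")
  expect_equal(fc2$summary$wilcoxon_p, 1)
  expect_true(is.na(fc2$summary$pearson_r))
  expect_true(all(fc2$variants$norm_diff == 0))
})

test_that("planted panel enrichment yields the inverse frequency relationship", {
  set.seed(68)
  hits <- 0L
  for (rep in 1:20) {
    panel <- simulate_breed_panel(sim_config(n_panel_variants = 100))
    fc <- frequency_contrast(genotyping_qc(panel)$panel)
    hits <- hits + (fc$summary$pearson_r < -0.3)
  }
  expect_gte(hits, 18)
})
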