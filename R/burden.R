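#' Classify sequencing variants as case-only / control-only / shared
#'
#' A variant is case-only when the alternate allele is carried by at least
#' one case, by zero controls, and the genotype is non-missing in at least
#' `control_callrate_min` of controls (so that missingness cannot
#' masquerade as absence); control-only is symmetric. Variants whose alt
#' allele appears in both groups, or in neither, are shared; variants
#' specific to one group but failing the other group's call-rate
#' requirement are private-missing. Variants missing in all dogs are
#' excluded with a log message.
#'
#' @param vt a [new_variant_table()] object.
#' @param control_callrate_min required called fraction in the opposite
#'   group (default 1 = fully genotyped).
#' @return The variant table with `status`, `n_case_carriers`,
#'   `n_control_carriers`, `case_called`, `control_called` columns added to
#'   `$variants`.
#' @export
classify_variants <- function(vt, control_callrate_min = 1) {
  stopifnot(inherits(vt, "variant_table"))
  dogs <- vt$dogs
  if (!any(dogs$group == "case") || !any(dogs$group == "control")) {
    abort("need at least one case and one control dog")
  }
  tall <- vt$calls %>% left_join(select(dogs, "dog", "group"), by = "dog")
  per <- tall %>%
    group_by(.data$variant_id) %>%
    summarise(
      n_case_carriers = sum(.data$gt > 0 & .data$group == "case", na.rm = TRUE),
      n_control_carriers = sum(.data$gt > 0 & .data$group == "control",
                               na.rm = TRUE),
      case_called = mean(!is.na(.data$gt[.data$group == "case"])),
      control_called = mean(!is.na(.data$gt[.data$group == "control"])),
      all_missing = all(is.na(.data$gt)),
      .groups = "drop"
    )
  n_drop <- sum(per$all_missing)
  if (n_drop > 0) {
    inform(paste(n_drop, "variant(s) missing in all dogs excluded"))
  }
  per <- per %>%
    filter(!.data$all_missing) %>%
    mutate(status = case_when(
      .data$n_case_carriers > 0 & .data$n_control_carriers == 0 &
        .data$control_called >= control_callrate_min ~ "case-only",
      .data$n_control_carriers > 0 & .data$n_case_carriers == 0 &
        .data$case_called >= control_callrate_min ~ "control-only",
      .data$n_case_carriers > 0 & .data$n_control_carriers == 0 ~
        "private-missing",
      .data$n_control_carriers > 0 & .data$n_case_carriers == 0 ~
        "private-missing",
      TRUE ~ "shared"
    )) %>%
    select(-"all_missing")
  vt$variants <- vt$variants %>%
    inner_join(per, by = "variant_id")
  vt$calls <- semi_join(vt$calls, vt$variants, by = "variant_id")
  vt
}

#' Flag variants inside constrained elements
#'
#' Sets a `constrained` flag on each variant: TRUE when its position lies
#' inside any element, using the 0-based half-open convention (a variant at
#' an element's start coordinate is inside; one at the end coordinate is
#' not).
#'
#' @param vt a `variant_table`.
#' @param elements tibble `chrom`, `start`, `end` (0-based half-open), as
#'   read by [read_bed()].
#' @return The variant table with a `constrained` logical column.
#' @export
intersect_constrained <- function(vt, elements) {
  stopifnot(inherits(vt, "variant_table"))
  v <- vt$variants
  hits <- overlap_pairs(
    tibble(chrom = v$chrom, start = v$pos, end = v$pos + 1),
    elements
  )
  vt$variants <- v %>%
    mutate(constrained = row_number() %in% hits$i)
  vt
}

# Exact two-sided rank-sum test by enumeration over group assignments,
# using midranks so ties are handled; falls back to the normal
# approximation with tie correction for larger groups.
rank_sum_test <- function(x, y, exact_max = 10) {
  n <- length(x); m <- length(y)
  if (n < 2 || m < 2) abort("need at least 2 observations per group")
  all_v <- c(x, y)
  r <- rank(all_v)
  w_obs <- sum(r[seq_len(n)])
  e_w <- n * (n + m + 1) / 2
  if (max(n, m) <= exact_max && choose(n + m, n) <= 2e5) {
    combs <- combn(n + m, n)
    w_all <- colSums(matrix(r[combs], nrow = n))
    p <- mean(abs(w_all - e_w) >= abs(w_obs - e_w) - 1e-9)
    method <- "exact"
  } else {
    ties <- table(r)
    sigma2 <- n * m / 12 * ((n + m + 1) -
                              sum(ties^3 - ties) / ((n + m) * (n + m - 1)))
    z <- (w_obs - e_w) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal"
  }
  tibble(statistic = w_obs, p = min(p, 1), method = method,
         n_x = n, n_y = m)
}

#' Per-dog count comparison of group-specific variants
#'
#' Counts, for each case dog, the case-only variants it carries and, for
#' each control dog, the control-only variants it carries (optionally
#' restricted to constrained elements and/or excluding coding variants),
#' then compares the two count vectors with a two-sided Wilcoxon rank-sum
#' test (exact enumeration with midranks for groups of up to 10 dogs,
#' normal approximation with tie correction above).
#'
#' @param vt a classified `variant_table` (see [classify_variants()]).
#' @param exclude character vector of dog ids to drop (e.g. a pair with
#'   unreliable calls) before counting.
#' @param constrained_only restrict to variants with `constrained = TRUE`.
#' @param exclude_coding drop variants with coding consequences (missense,
#'   nonsense, frameshift, silent, UTR, splice).
#' @return A list of class `dog_count_test` with `counts` (tibble `dog`,
#'   `group`, `n`) and `test` (tibble `median_case`, `median_control`,
#'   `statistic`, `p`, `method`).
#' @export
per_dog_count_test <- function(vt, exclude = character(),
                               constrained_only = FALSE,
                               exclude_coding = FALSE) {
  stopifnot(inherits(vt, "variant_table"))
  if (!"status" %in% names(vt$variants)) {
    abort("run classify_variants() first")
  }
  v <- vt$variants
  if (constrained_only) {
    if (!"constrained" %in% names(v)) abort("run intersect_constrained() first")
    v <- filter(v, .data$constrained)
  }
  if (exclude_coding) {
    v <- filter(v, !.data$consequence %in%
                  c("missense", "nonsense", "frameshift", "silent", "UTR",
                    "splice"))
  }
  dogs <- vt$dogs %>% filter(!.data$dog %in% exclude)
  if (sum(dogs$group == "case") < 2 || sum(dogs$group == "control") < 2) {
    abort("need at least 2 dogs per group after exclusions")
  }
  carried <- vt$calls %>%
    filter(.data$dog %in% dogs$dog, !is.na(.data$gt), .data$gt > 0) %>%
    inner_join(select(v, "variant_id", "status"), by = "variant_id") %>%
    left_join(select(dogs, "dog", "group"), by = "dog") %>%
    filter((.data$group == "case" & .data$status == "case-only") |
             (.data$group == "control" & .data$status == "control-only")) %>%
    count(.data$dog, name = "n")
  counts <- dogs %>%
    left_join(carried, by = "dog") %>%
    mutate(n = dplyr::coalesce(.data$n, 0L)) %>%
    select("dog", "group", "n")
  xs <- counts$n[counts$group == "case"]
  ys <- counts$n[counts$group == "control"]
  tst <- rank_sum_test(xs, ys) %>%
    mutate(median_case = median(xs), median_control = median(ys)) %>%
    relocate("median_case", "median_control")
  structure(list(counts = counts, test = tst), class = "dog_count_test")
}

#' @export
print.dog_count_test <- function(x, ...) {
  cat("<dog_count_test> median case ", x$test$median_case, " vs control ",
      x$test$median_control, "; P = ", signif(x$test$p, 3), " (",
      x$test$method, ")\n", sep = "")
  invisible(x)
}

#' @export
tidy.dog_count_test <- function(x, ...) x$counts

#' @export
glance.dog_count_test <- function(x, ...) x$test

#' Gene-based burden of case-only versus control-only variants
#'
#' Counts case-only and control-only variants within each gene's span plus
#' a flank on each side, overall and restricted to constrained elements,
#' and forms the size-corrected ratio (case-only + 1) / (control-only + 1)
#' (the pseudocount lets genes with zero control-only variants be ranked;
#' raw counts are always reported so the unmodified ratio is recoverable).
#' Genes are ranked by the constrained-element ratio, then by constrained
#' case-only count.
#'
#' @param vt a classified `variant_table` with constrained flags.
#' @param gene_catalog tibble `gene`, `chrom`, `start`, `end`.
#' @param flank flank in bp (default 5 kb).
#' @return A tibble of class `gene_burden`: `gene`, `case_only`,
#'   `control_only`, `case_only_constrained`, `control_only_constrained`,
#'   `ratio`, `ratio_constrained`, `rank`.
#' @export
gene_burden <- function(vt, gene_catalog, flank = 5000) {
  stopifnot(inherits(vt, "variant_table"))
  if (!nrow(gene_catalog)) abort("gene catalog is empty")
  if (!"status" %in% names(vt$variants)) abort("run classify_variants() first")
  v <- vt$variants
  if (!"constrained" %in% names(v)) v <- mutate(v, constrained = FALSE)
  spans <- gene_catalog %>%
    mutate(start = pmax(0, .data$start - flank), end = .data$end + flank)
  hits <- overlap_pairs(
    tibble(chrom = v$chrom, start = v$pos, end = v$pos + 1),
    spans
  )
  tallies <- tibble(
    gene = gene_catalog$gene[hits$j],
    status = v$status[hits$i],
    constrained = v$constrained[hits$i]
  ) %>%
    group_by(.data$gene) %>%
    summarise(
      case_only = sum(.data$status == "case-only"),
      control_only = sum(.data$status == "control-only"),
      case_only_constrained = sum(.data$status == "case-only" &
                                    .data$constrained),
      control_only_constrained = sum(.data$status == "control-only" &
                                       .data$constrained),
      .groups = "drop"
    )
  out <- gene_catalog %>%
    select("gene") %>%
    left_join(tallies, by = "gene") %>%
    mutate(dplyr::across(-"gene", ~ dplyr::coalesce(.x, 0L))) %>%
    mutate(
      ratio = (.data$case_only + 1) / (.data$control_only + 1),
      ratio_constrained = (.data$case_only_constrained + 1) /
        (.data$control_only_constrained + 1)
    ) %>%
    arrange(desc(.data$ratio_constrained),
            desc(.data$case_only_constrained)) %>%
    mutate(rank = row_number())
  class(out) <- c("gene_burden", class(out))
  out
}

#' Gene burden with one breed left out
#'
#' Removes the named breed's dogs, re-classifies variants on the remaining
#' panel and recomputes the gene burden — used to check that a burden
#' signal does not depend on the breed that drove gene discovery.
#'
#' @param vt a `variant_table` (classification is redone after removal).
#' @param breed breed to remove.
#' @param gene_catalog,flank passed to [gene_burden()].
#' @param constrained tibble of constrained elements (re-intersected after
#'   removal); omit if `vt` has no constrained flags.
#' @param control_callrate_min passed to [classify_variants()].
#' @return A `gene_burden` tibble for the reduced panel.
#' @export
leave_breed_out <- function(vt, breed, gene_catalog, flank = 5000,
                            constrained = NULL, control_callrate_min = 1) {
  stopifnot(inherits(vt, "variant_table"))
  keep <- vt$dogs$dog[vt$dogs$breed != breed]
  sub <- subset_dogs(vt, keep)
  if (!any(sub$dogs$group == "case") || !any(sub$dogs$group == "control")) {
    abort("removing this breed empties a phenotype group")
  }
  sub <- classify_variants(sub, control_callrate_min = control_callrate_min)
  if (!is.null(constrained)) sub <- intersect_constrained(sub, constrained)
  gene_burden(sub, gene_catalog, flank = flank)
}

#' Select candidate variants for follow-up genotyping
#'
#' Applies the panel-design criteria and returns the union of variants
#' meeting any enabled one, each labelled with its qualifying criteria:
#' (i) case-only variants in the target breed; (ii) case-only variants in
#' the named burden genes (span + flank); (iii) case-only variants carried
#' in at least two breeds; (iv) potential functional variants (nonsense,
#' splice or missense) that are case-only; (v) variants inside the risk
#' haplotype interval; (vi) variants at top associated SNP positions.
#' Criteria i-iii are restricted to variants in constrained elements.
#'
#' @param vt a classified `variant_table` with constrained flags.
#' @param gene_catalog tibble `gene`, `chrom`, `start`, `end`.
#' @param burden_genes character vector of gene ids for criterion ii.
#' @param target_breed breed name for criterion i.
#' @param assoc optional association tibble for criterion vi.
#' @param assoc_p P-value cutoff defining "top associated" SNPs.
#' @param risk_region optional list/tibble `chrom`, `start`, `end` for
#'   criterion v.
#' @param criteria subset of c("i","ii","iii","iv","v","vi") to enable.
#' @param flank flank around burden genes in bp.
#' @return A tibble of candidate variants with a `criteria` character
#'   column (comma-separated roman labels).
#' @export
select_candidates <- function(vt, gene_catalog, burden_genes = character(),
                              target_breed = NULL, assoc = NULL,
                              assoc_p = 1e-4, risk_region = NULL,
                              criteria = c("i", "ii", "iii", "iv", "v", "vi"),
                              flank = 5000) {
  stopifnot(inherits(vt, "variant_table"))
  v <- vt$variants
  if (!all(c("status", "constrained") %in% names(v))) {
    abort("classify_variants() and intersect_constrained() must run first")
  }
  unknown <- setdiff(burden_genes, gene_catalog$gene)
  if (length(unknown)) {
    abort(paste("unknown gene name(s):", paste(unknown, collapse = ", ")))
  }
  carriers <- vt$calls %>%
    filter(!is.na(.data$gt), .data$gt > 0) %>%
    left_join(vt$dogs, by = "dog")
  carrier_breeds <- carriers %>%
    group_by(.data$variant_id) %>%
    summarise(n_breeds = dplyr::n_distinct(.data$breed),
              in_target = if (is.null(target_breed)) FALSE else
                any(.data$breed == target_breed),
              .groups = "drop")
  v <- v %>% left_join(carrier_breeds, by = "variant_id") %>%
    mutate(n_breeds = dplyr::coalesce(.data$n_breeds, 0L),
           in_target = dplyr::coalesce(.data$in_target, FALSE))
  caseonly <- v$status == "case-only"

  crit <- list()
  if ("i" %in% criteria && !is.null(target_breed)) {
    crit$i <- caseonly & v$constrained & v$in_target
  }
  if ("ii" %in% criteria && length(burden_genes)) {
    spans <- gene_catalog %>%
      filter(.data$gene %in% burden_genes) %>%
      mutate(start = pmax(0, .data$start - flank), end = .data$end + flank)
    hits <- overlap_pairs(tibble(chrom = v$chrom, start = v$pos,
                                 end = v$pos + 1), spans)
    in_gene <- seq_len(nrow(v)) %in% hits$i
    crit$ii <- caseonly & v$constrained & in_gene
  }
  if ("iii" %in% criteria) {
    crit$iii <- caseonly & v$constrained & v$n_breeds >= 2
  }
  if ("iv" %in% criteria) {
    crit$iv <- caseonly & v$consequence %in% c("nonsense", "splice", "missense")
  }
  if ("v" %in% criteria && !is.null(risk_region)) {
    crit$v <- v$chrom == risk_region$chrom &
      v$pos >= risk_region$start & v$pos < risk_region$end
  }
  if ("vi" %in% criteria && !is.null(assoc)) {
    top <- assoc %>% filter(.data$p < assoc_p)
    crit$vi <- paste(v$chrom, v$pos) %in% paste(top$chrom, top$pos)
  }
  if (!length(crit)) return(v[0, ])
  lab <- vapply(seq_len(nrow(v)), function(i) {
    hit <- names(crit)[vapply(crit, function(z) z[i], logical(1))]
    paste(hit, collapse = ",")
  }, character(1))
  v %>%
    mutate(criteria = lab) %>%
    filter(nchar(.data$criteria) > 0)
}

#' Quality-control a genotyping breed panel
#'
#' Removes samples with missing genotype rate above `max_sample_missing`,
#' then variants with call rate below `min_snp_callrate`, and reports every
#' removal.
#'
#' @param panel a [new_breed_panel()].
#' @param max_sample_missing sample missingness cutoff (remove if strictly
#'   greater).
#' @param min_snp_callrate variant call-rate cutoff (remove if strictly
#'   lower).
#' @return A list with `panel` (cleaned) and `report` (tibble `step`,
#'   `entity`, `id`, `reason`, `value`).
#' @export
genotyping_qc <- function(panel, max_sample_missing = 0.10,
                          min_snp_callrate = 0.90) {
  stopifnot(inherits(panel, "breed_panel"))
  if (!length(panel$gt)) abort("empty panel")
  report <- list()
  miss <- rowMeans(is.na(panel$gt))
  drop_dog <- miss > max_sample_missing
  if (any(drop_dog)) {
    report$dogs <- tibble(step = 1L, entity = "sample",
                          id = rownames(panel$gt)[drop_dog],
                          reason = "sample_missing_rate",
                          value = miss[drop_dog])
    panel <- new_breed_panel(panel$gt[!drop_dog, , drop = FALSE],
                             panel$variants,
                             panel$dogs[!drop_dog, , drop = FALSE])
  }
  cr <- colMeans(!is.na(panel$gt))
  drop_snp <- cr < min_snp_callrate
  if (any(drop_snp)) {
    report$snps <- tibble(step = 2L, entity = "variant",
                          id = colnames(panel$gt)[drop_snp],
                          reason = "variant_call_rate",
                          value = cr[drop_snp])
    panel <- new_breed_panel(panel$gt[, !drop_snp, drop = FALSE],
                             panel$variants[!drop_snp, , drop = FALSE],
                             panel$dogs)
  }
  if (!nrow(panel$gt) || !ncol(panel$gt)) abort("panel empty after QC")
  report_tbl <- if (length(report)) list_rbind(unname(report)) else tibble(
    step = integer(), entity = character(), id = character(),
    reason = character(), value = numeric())
  list(panel = panel, report = report_tbl)
}

#' Normalized allele-frequency difference
#'
#' The bounded contrast (a - b) / (a + b) in \[-1, 1\] between two group
#' allele frequencies; exactly antisymmetric. When both frequencies are
#' zero the value is undefined and returned as NA (callers exclude such
#' variants with a flag).
#'
#' @param af_risk,af_ctrl allele frequencies in \[0, 1\] (vectorized).
#' @return Numeric vector in \[-1, 1\], NA where both inputs are zero.
#' @export
normalized_af_diff <- function(af_risk, af_ctrl) {
  if (any(af_risk < 0 | af_risk > 1 | af_ctrl < 0 | af_ctrl > 1,
          na.rm = TRUE)) {
    abort("allele frequencies must lie in [0, 1]",
          class = "breedmap_input_error")
  }
  s <- af_risk + af_ctrl
  ifelse(s == 0, NA_real_, (af_risk - af_ctrl) / s)
}

#' Breed-group allele-frequency contrast
#'
#' Computes per-variant allele frequencies in risk and control breed
#' groups, their medians, a two-sided Wilcoxon signed-rank test on the
#' paired per-variant frequencies, and the Pearson correlation between the
#' overall allele frequency and the normalized frequency difference
#' (with its test P-value). Variants with zero frequency in both groups
#' have an undefined normalized difference and are excluded from the
#' correlation with a flag.
#'
#' @param panel a (QC'd) [new_breed_panel()].
#' @param min_variants minimum number of variants required.
#' @return A list of class `freq_contrast`: `variants` (per-variant tibble
#'   `variant_id`, `af_risk`, `af_ctrl`, `af_all`, `norm_diff`,
#'   `excluded`) and `summary` (one-row tibble `median_risk`,
#'   `median_ctrl`, `wilcoxon_p`, `pearson_r`, `pearson_p`, `n_variants`,
#'   `n_excluded`).
#' @export
frequency_contrast <- function(panel, min_variants = 5) {
  stopifnot(inherits(panel, "breed_panel"))
  if (ncol(panel$gt) < min_variants) {
    abort(paste("need at least", min_variants, "variants"))
  }
  grp_af <- function(rows) {
    called <- colSums(!is.na(panel$gt[rows, , drop = FALSE]))
    alt <- colSums(panel$gt[rows, , drop = FALSE], na.rm = TRUE)
    unname(ifelse(called > 0, alt / (2 * called), NA_real_))
  }
  risk <- which(panel$dogs$breed_class == "risk")
  ctrl <- which(panel$dogs$breed_class == "control_breed")
  af_risk <- grp_af(risk)
  af_ctrl <- grp_af(ctrl)
  af_all <- grp_af(seq_len(nrow(panel$gt)))
  nd <- normalized_af_diff(af_risk, af_ctrl)
  variants <- tibble(
    variant_id = colnames(panel$gt),
    af_risk = af_risk, af_ctrl = af_ctrl, af_all = af_all,
    norm_diff = nd,
    excluded = is.na(nd)
  )
  d <- af_risk - af_ctrl
  if (all(abs(d) < 1e-15)) {
    w_p <- 1
  } else {
    w_p <- suppressWarnings(
      wilcox.test(af_risk, af_ctrl, paired = TRUE, exact = FALSE)$p.value
    )
  }
  ok <- !variants$excluded
  if (sd(af_all[ok]) < 1e-12 || sd(nd[ok]) < 1e-12) {
    r <- NA_real_; r_p <- NA_real_
    warn("degenerate frequency vectors; correlation undefined")
  } else {
    ct <- cor.test(af_all[ok], nd[ok])
    r <- unname(ct$estimate); r_p <- ct$p.value
  }
  summary <- tibble(
    median_risk = median(af_risk, na.rm = TRUE),
    median_ctrl = median(af_ctrl, na.rm = TRUE),
    wilcoxon_p = w_p,
    pearson_r = r,
    pearson_p = r_p,
    n_variants = ncol(panel$gt),
    n_excluded = sum(variants$excluded)
  )
  structure(list(variants = variants, summary = summary),
            class = "freq_contrast")
}

#' @export
print.freq_contrast <- function(x, ...) {
  s <- x$summary
  cat("<freq_contrast> median AF risk ", signif(s$median_risk, 3),
      " vs control ", signif(s$median_ctrl, 3),
      " (Wilcoxon P = ", signif(s$wilcoxon_p, 3), ")\n",
      "  Pearson r(overall AF, normalized diff) = ", signif(s$pearson_r, 3),
      " (P = ", signif(s$pearson_p, 3), ")\n", sep = "")
  invisible(x)
}

#' @export
tidy.freq_contrast <- function(x, ...) x$variants

#' @export
glance.freq_contrast <- function(x, ...) x$summary
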