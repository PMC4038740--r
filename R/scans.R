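#' Scan one breed for regions of fixation
#'
#' Finds all maximal SNP intervals whose genomic span exceeds `min_span`
#' bp, which contain more than `min_snps` SNPs, and in which the fraction
#' of SNPs with within-breed MAF below `maf_thresh` exceeds `min_frac`.
#' An interval is maximal when extending it by the adjacent SNP on either
#' side would violate one of the criteria (the low-MAF fraction is not
#' monotone, so maximal intervals are found by exhaustive enumeration over
#' SNP index pairs with prefix sums). Because the fraction criterion is not
#' monotone, several maximal intervals can overlap; the report keeps one
#' representative per overlap cluster (most SNPs, then highest low-MAF
#' fraction, then leftmost) so that regions are disjoint while every
#' reported region itself satisfies the printed criteria. All maximal
#' intervals are kept in the `intervals` attribute.
#'
#' @param geno a [new_geno()] object holding one breed's genotypes (SNP
#'   order within the input is irrelevant; sorting is internal).
#' @param min_span minimum genomic span in bp (strict, first to last SNP).
#' @param min_snps minimum SNP count (strict, i.e. more than `min_snps`).
#' @param maf_thresh MAF below which a SNP counts as (near-)fixed (strict).
#' @param min_frac required fraction of low-MAF SNPs (strict).
#' @return A tibble of class `region_set` with columns `chrom`, `start`,
#'   `end` (half-open, last SNP position + 1), `label`, `score` (low-MAF
#'   fraction), `n_snps`, `members`.
#' @export
fixation_scan <- function(geno, min_span = 1e6, min_snps = 5,
                          maf_thresh = 0.05, min_frac = 0.95) {
  fr <- snp_freq(geno) %>% arrange(.data$chrom, .data$pos)
  out <- list()
  for (ch in unique(fr$chrom)) {
    sub <- filter(fr, .data$chrom == ch)
    n <- nrow(sub)
    if (n < 2) next
    low <- as.integer(!is.na(sub$maf) & sub$maf < maf_thresh)
    cum <- c(0L, cumsum(low))
    pos <- sub$pos
    # qualifying (i, j): span, count and fraction criteria
    qual <- function(i, j) {
      cnt <- j - i + 1
      (pos[j] - pos[i]) > min_span & cnt > min_snps &
        (cum[j + 1] - cum[i]) / cnt > min_frac
    }
    ij <- which(outer(seq_len(n), seq_len(n), function(i, j) {
      j > i & qual(pmin(i, j), pmax(i, j)) & i < j
    }), arr.ind = TRUE)
    ij <- ij[ij[, 1] < ij[, 2], , drop = FALSE]
    if (!nrow(ij)) next
    i <- ij[, 1]; j <- ij[, 2]
    maximal <- !(ifelse(i > 1, qual(pmax(i - 1, 1), j), FALSE)) &
      !(ifelse(j < n, qual(i, pmin(j + 1, n)), FALSE))
    ij <- ij[maximal, , drop = FALSE]
    if (!nrow(ij)) next
    ivs <- tibble(
      chrom = ch,
      start = pos[ij[, 1]],
      end = pos[ij[, 2]] + 1L,
      n_snps = ij[, 2] - ij[, 1] + 1L,
      frac_low = (cum[ij[, 2] + 1] - cum[ij[, 1]]) / (ij[, 2] - ij[, 1] + 1L),
      i = ij[, 1], j = ij[, 2]
    ) %>% arrange(.data$start)
    # group overlapping maximal intervals and keep one representative each
    cluster <- cumsum(c(1, as.integer(
      ivs$start[-1] >= cummax(ivs$end[-nrow(ivs)]))))
    picked <- ivs %>%
      mutate(cluster = cluster) %>%
      group_by(.data$cluster) %>%
      arrange(desc(.data$n_snps), desc(.data$frac_low), .data$start,
              .by_group = TRUE) %>%
      slice(1) %>%
      ungroup() %>%
      arrange(.data$start) %>%
      select(-"cluster")
    mg <- picked %>%
      mutate(members = purrr::map2(.data$i, .data$j, function(a, b) sub$snp[a:b])) %>%
      select(-"i", -"j")
    out[[ch]] <- mg
    attr(out[[ch]], "unmerged") <- ivs
  }
  if (!length(out)) {
    res <- tibble(chrom = character(), start = numeric(), end = numeric(),
                  label = character(), score = numeric(), n_snps = integer(),
                  members = list())
    class(res) <- c("region_set", class(res))
    return(res)
  }
  unmerged <- purrr::map(out, function(o) attr(o, "unmerged")) %>%
    list_rbind()
  res <- list_rbind(unname(out)) %>%
    mutate(label = sprintf("fix%02d", row_number()),
           score = .data$frac_low) %>%
    select("chrom", "start", "end", "label", "score", "n_snps", "members")
  attr(res, "intervals") <- unmerged
  class(res) <- c("region_set", class(res))
  res
}

#' Post-hoc validator for fixation regions
#'
#' Independently re-checks every reported region against the printed
#' criteria using only the region coordinates and the raw genotypes.
#'
#' @inheritParams fixation_scan
#' @param regions output of [fixation_scan()].
#' @return TRUE invisibly; aborts on any violation.
#' @export
validate_fixed_regions <- function(regions, geno, min_span = 1e6,
                                   min_snps = 5, maf_thresh = 0.05,
                                   min_frac = 0.95) {
  fr <- snp_freq(geno)
  for (r in seq_len(nrow(regions))) {
    inside <- fr$chrom == regions$chrom[r] &
      fr$pos >= regions$start[r] & fr$pos < regions$end[r]
    mafs <- fr$maf[inside]
    span <- max(fr$pos[inside]) - min(fr$pos[inside])
    if (span <= min_span) abort("fixation region span too small")
    if (sum(inside) <= min_snps) abort("fixation region has too few SNPs")
    if (mean(mafs < maf_thresh, na.rm = TRUE) <= min_frac) {
      abort("fixation region fails the low-MAF fraction")
    }
  }
  invisible(TRUE)
}

window_heterozygosity <- function(geno, width, chrom_length) {
  fr <- snp_freq(geno)
  fr %>%
    mutate(window = floor(.data$pos / width)) %>%
    group_by(.data$chrom, .data$window) %>%
    summarise(het = mean(2 * .data$af * (1 - .data$af), na.rm = TRUE),
              n_snps = sum(!is.na(.data$af)), .groups = "drop") %>%
    mutate(start = .data$window * width,
           end = pmin((.data$window + 1) * width, chrom_length))
}

#' Scan for regions of reduced variability (RRVs)
#'
#' Tiles the genome in non-overlapping fixed-width windows, scores each
#' window's variability as the mean expected heterozygosity 2p(1-p) over
#' its SNPs, and compares the target breed to the mean of the reference
#' breeds: relative score = target / (mean reference + epsilon). The
#' floor(quantile x W) windows with the lowest relative score are reported
#' (W = number of windows retained after dropping SNP-less windows), with
#' ties broken by position; adjacent selected windows are merged into
#' regions when `merge_adjacent` is TRUE.
#'
#' @param target a [new_geno()] object for the target breed.
#' @param references a [new_geno()] object whose sample sheet has a
#'   `breed` column covering the reference breeds.
#' @param window window width in bp (default 150 kb).
#' @param quantile fraction of windows to report (default 1%).
#' @param epsilon stabilizer added to the reference mean so reference-fixed
#'   windows do not produce infinite ratios.
#' @param chrom_length chromosome length in bp; defaults to the last SNP
#'   position + 1.
#' @param merge_adjacent merge adjacent selected windows in the region
#'   output.
#' @param mode "relative" (ratio to reference mean) or "absolute" (target
#'   heterozygosity alone).
#' @param shrink number of pseudo-SNPs at the genome-average heterozygosity
#'   added to each window's target and reference means before forming the
#'   ratio. The default 0 is the plain mean-heterozygosity score. With
#'   sparse maps (one or two SNPs per window) and called genotypes, a small
#'   positive value (1 is sensible) regularizes the score by SNP support,
#'   so a ten-SNP zero-heterozygosity window outranks a single drifted or
#'   miscalled monomorphic SNP.
#' @return A list of class `rrv_scan` with `windows` (all retained windows
#'   with scores and a `selected` flag), `selected` (exactly
#'   floor(quantile x W) rows) and `regions` (tibble of class `region_set`).
#' @export
rrv_scan <- function(target, references, window = 150e3, quantile = 0.01,
                     epsilon = 1e-6, chrom_length = NULL,
                     merge_adjacent = TRUE, mode = c("relative", "absolute"),
                     shrink = 0) {
  mode <- match.arg(mode)
  if (is.null(chrom_length)) {
    chrom_length <- max(target$snps$pos) + 1
  }
  tw <- window_heterozygosity(target, window, chrom_length) %>%
    rename(het_target = "het", n_target = "n_snps")
  ref_breeds <- unique(references$samples$breed)
  if (!length(ref_breeds)) abort("need at least one reference breed")
  rw <- purrr::map(ref_breeds, function(b) {
    g <- subset_geno(references, samples = references$samples$breed == b)
    window_heterozygosity(g, window, chrom_length) %>%
      mutate(breed = b)
  }) %>% list_rbind() %>%
    group_by(.data$chrom, .data$window) %>%
    summarise(het_ref = mean(.data$het, na.rm = TRUE), .groups = "drop")

  win <- tw %>%
    left_join(rw, by = c("chrom", "window")) %>%
    filter(.data$n_target > 0, !is.na(.data$het_target))
  n_dropped <- nrow(tw) - nrow(win)
  if (n_dropped > 0) inform(paste(n_dropped, "window(s) without SNPs dropped"))
  if (shrink > 0) {
    h0_t <- sum(win$het_target * win$n_target) / sum(win$n_target)
    h0_r <- sum(win$het_ref * win$n_target, na.rm = TRUE) / sum(win$n_target)
    win <- win %>%
      mutate(
        het_target_s = (.data$het_target * .data$n_target + shrink * h0_t) /
          (.data$n_target + shrink),
        het_ref_s = (.data$het_ref * .data$n_target + shrink * h0_r) /
          (.data$n_target + shrink)
      )
  } else {
    win <- win %>% mutate(het_target_s = .data$het_target,
                          het_ref_s = .data$het_ref)
  }
  win <- win %>%
    mutate(score = if (mode == "relative") {
      .data$het_target_s / (.data$het_ref_s + epsilon)
    } else .data$het_target_s)
  n_sel <- floor(quantile * nrow(win))
  # ties (typically several windows at score 0) are resolved in favour of
  # windows supported by more SNPs: a 10-SNP zero-heterozygosity window is
  # far stronger evidence than a single drifted SNP
  ord <- order(win$score, -win$n_target, win$chrom, win$start)
  sel_idx <- head(ord, n_sel)
  win$selected <- FALSE
  win$selected[sel_idx] <- TRUE
  selected <- win[sort(sel_idx), ]

  regions <- selected
  if (merge_adjacent && nrow(selected) > 1) {
    regions <- selected %>%
      arrange(.data$chrom, .data$start) %>%
      group_by(.data$chrom) %>%
      mutate(gap = .data$start - dplyr::lag(.data$end, default = -1),
             grp = cumsum(.data$gap != 0)) %>%
      group_by(.data$chrom, .data$grp) %>%
      summarise(start = min(.data$start), end = max(.data$end),
                score = min(.data$score), n_windows = n(), .groups = "drop") %>%
      select(-"grp")
  } else if (nrow(selected)) {
    regions <- selected %>%
      select("chrom", "start", "end", "score") %>%
      mutate(n_windows = 1L)
  } else {
    regions <- tibble(chrom = character(), start = numeric(), end = numeric(),
                      score = numeric(), n_windows = integer())
  }
  regions <- regions %>%
    mutate(label = sprintf("rrv%02d", row_number())) %>%
    relocate("chrom", "start", "end", "label", "score")
  class(regions) <- c("region_set", class(regions))
  structure(list(windows = win, selected = selected, regions = regions,
                 window_width = window, quantile = quantile, mode = mode),
            class = "rrv_scan")
}

#' @export
print.rrv_scan <- function(x, ...) {
  cat("<rrv_scan> ", nrow(x$windows), " windows of ", x$window_width / 1e3,
      " kb; ", nrow(x$selected), " selected (quantile ", x$quantile, ")\n",
      sep = "")
  invisible(x)
}

#' @export
tidy.rrv_scan <- function(x, ...) x$windows

#' Breed-differential gene-set enrichment scoring
#'
#' Given per-set enrichment P-values for the target breed and for each
#' reference breed, candidate sets are those with target P below `p_max`
#' and at least `min_genes` target RRV genes. Each candidate's score is the
#' mean over reference breeds of (P_reference - P_target); sets whose
#' target P is smaller than every reference breed's P are flagged as more
#' enriched in the target than in any other breed.
#'
#' @param target tibble with columns `set`, `p` (target-breed enrichment).
#' @param references long tibble with columns `set`, `breed`, `p`; missing
#'   (NA) reference P-values drop that breed from the mean, with a log
#'   message.
#' @param rrv_genes tibble with columns `set`, `n_genes` (number of
#'   target-breed RRV genes in the set).
#' @param p_max candidate threshold on the target P.
#' @param min_genes minimum RRV gene count.
#' @return A tibble `set`, `p_target`, `n_rrv_genes`, `n_ref`, `score`,
#'   `flagged`, sorted by decreasing score.
#' @export
differential_set_enrichment <- function(target, references, rrv_genes,
                                        p_max = 0.05, min_genes = 2) {
  cand <- target %>%
    rename(p_target = "p") %>%
    inner_join(rrv_genes, by = "set") %>%
    filter(.data$p_target < p_max, .data$n_genes >= min_genes)
  if (anyNA(references$p)) {
    inform(paste(sum(is.na(references$p)),
                 "missing reference P-value(s) dropped from the mean"))
  }
  refs <- references %>%
    filter(!is.na(.data$p)) %>%
    group_by(.data$set) %>%
    summarise(n_ref = n(), mean_ref = mean(.data$p), min_ref = min(.data$p),
              .groups = "drop")
  cand %>%
    left_join(refs, by = "set") %>%
    mutate(score = .data$mean_ref - .data$p_target,
           flagged = .data$p_target < .data$min_ref,
           n_rrv_genes = .data$n_genes) %>%
    select("set", "p_target", "n_rrv_genes", "n_ref", "score", "flagged") %>%
    arrange(desc(.data$score))
}
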