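#' Case/control allelic chi-squared association test
#'
#' For each SNP, alleles of cases and controls are cross-tabulated in a
#' 2 x 2 (allele x status) table and tested with the 1-df chi-squared
#' statistic without continuity correction,
#' N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d)). Missing genotypes are excluded
#' per SNP. Monomorphic SNPs (or empty margins) get statistic 0, P = 1 and
#' a flag.
#'
#' @param geno a [new_geno()] object whose sample sheet has a `group`
#'   column with values "case"/"control" (other samples are ignored), or a
#'   genotype matrix plus `phenotype`.
#' @param phenotype optional character vector ("case"/"control") aligned
#'   with the rows of `geno` when `geno` is a bare matrix.
#' @return A tibble of class `breedmap_assoc` with columns `snp`, `chrom`,
#'   `pos`, `case_alt`, `case_ref`, `ctrl_alt`, `ctrl_ref`, `maf`,
#'   `chi2`, `p`, `flag`.
#' @export
allelic_chisq <- function(geno, phenotype = NULL) {
  if (inherits(geno, "geno")) {
    gt <- geno$gt
    phenotype <- geno$samples$group
    snps <- geno$snps
  } else {
    gt <- as.matrix(geno)
    if (is.null(phenotype)) abort("phenotype required for a bare matrix")
    snps <- tibble(snp = colnames(gt) %||% paste0("snp", seq_len(ncol(gt))),
                   chrom = NA_character_, pos = NA_integer_)
  }
  case <- phenotype == "case"
  ctrl <- phenotype == "control"
  if (!any(case) || !any(ctrl)) abort("need at least one case and one control")

  count_alleles <- function(rows) {
    sub <- gt[rows, , drop = FALSE]
    called <- colSums(!is.na(sub))
    alt <- colSums(sub, na.rm = TRUE)
    list(alt = alt, ref = 2 * called - alt)
  }
  cs <- count_alleles(case)
  ct <- count_alleles(ctrl)
  a <- unname(cs$alt); b <- unname(cs$ref)
  c_ <- unname(ct$alt); d <- unname(ct$ref)
  n_tot <- a + b + c_ + d
  denom <- (a + b) * (c_ + d) * (a + c_) * (b + d)
  chi2 <- ifelse(denom > 0, n_tot * (a * d - b * c_)^2 / denom, 0)
  af <- (a + c_) / pmax(n_tot, 1)
  flag <- denom == 0
  chi2[flag] <- 0
  p <- pchisq(chi2, df = 1, lower.tail = FALSE)
  p[flag] <- 1
  out <- snps %>%
    select("snp", "chrom", "pos") %>%
    mutate(case_alt = a, case_ref = b, ctrl_alt = c_, ctrl_ref = d,
           maf = pmin(af, 1 - af), chi2 = chi2, p = p, flag = flag)
  class(out) <- c("breedmap_assoc", class(out))
  out
}

#' Squared LD correlation between genotype dosage vectors
#'
#' Squared Pearson correlation of allele-B dosages over pairwise-complete
#' samples. Undefined values (fewer than 3 complete pairs, or a
#' zero-variance vector) are returned as 0 with a flag attribute.
#'
#' @param x,y integer dosage vectors (0/1/2, NA allowed).
#' @return A number in \[0, 1\]; attribute `flag` is TRUE when the value
#'   was undefined and substituted with 0.
#' @export
ld_r2 <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3 || sd(x[ok]) == 0 || sd(y[ok]) == 0) {
    return(structure(0, flag = TRUE))
  }
  structure(unname(cor(x[ok], y[ok])^2), flag = FALSE)
}

# r^2 of one index dosage vector against each column of a dosage matrix
ld_r2_vec <- function(index, mat) {
  vapply(seq_len(ncol(mat)), function(j) as.numeric(ld_r2(index, mat[, j])),
         numeric(1))
}

#' LD clumping of association results into candidate regions
#'
#' Greedy clumping: among unassigned SNPs with P below `p_index`, the SNP
#' with the smallest P (ties broken by smaller position) becomes the index;
#' every unassigned SNP on the same chromosome within `window` bp of the
#' index with r^2 above `r2_min` and P below `p_member` joins its clump
#' (the index always belongs to its own clump). The clump's region spans
#' the minimum to maximum member position. This repeats until no index
#' SNP remains. Overlapping clump spans, should they arise, are merged so
#' the returned region set is disjoint.
#'
#' @param assoc output of [allelic_chisq()] (columns `snp`, `chrom`, `pos`,
#'   `p`).
#' @param geno the [new_geno()] object the association was computed from
#'   (used for dosage r^2).
#' @param p_index index-SNP P-value threshold.
#' @param p_member member-SNP P-value threshold.
#' @param r2_min minimum dosage r^2 with the index SNP (strictly greater).
#' @param window maximum index-to-member distance in bp (inclusive).
#' @return A tibble of class `region_set` with columns `chrom`, `start`,
#'   `end` (0-based half-open), `label`, `score` (index-SNP -log10 P),
#'   `index_snp`, `index_p`, `n_snps`, and a list column `members` of SNP
#'   ids. Empty when no SNP reaches `p_index`.
#' @export
clump <- function(assoc, geno, p_index = 1e-4, p_member = 0.01,
                  r2_min = 0.8, window = 1e6) {
  stopifnot(inherits(geno, "geno"))
  assoc <- arrange(as_tibble(assoc), .data$chrom, .data$pos)
  gt <- geno$gt[, assoc$snp, drop = FALSE]
  assigned <- rep(FALSE, nrow(assoc))
  regions <- list()
  repeat {
    cand <- which(!assigned & assoc$p < p_index)
    if (!length(cand)) break
    idx <- cand[order(assoc$p[cand], assoc$pos[cand])][1]
    near <- which(!assigned &
                    assoc$chrom == assoc$chrom[idx] &
                    abs(assoc$pos - assoc$pos[idx]) <= window &
                    assoc$p < p_member)
    near <- setdiff(near, idx)
    memb <- idx
    if (length(near)) {
      r2 <- ld_r2_vec(gt[, idx], gt[, near, drop = FALSE])
      memb <- c(idx, near[r2 > r2_min])
    }
    assigned[memb] <- TRUE
    regions[[length(regions) + 1]] <- tibble(
      chrom = assoc$chrom[idx],
      start = min(assoc$pos[memb]),
      end = max(assoc$pos[memb]) + 1L,
      index_snp = assoc$snp[idx],
      index_p = assoc$p[idx],
      n_snps = length(memb),
      members = list(assoc$snp[sort(memb)])
    )
  }
  if (!length(regions)) {
    out <- tibble(chrom = character(), start = numeric(), end = numeric(),
                  label = character(), score = numeric(),
                  index_snp = character(), index_p = numeric(),
                  n_snps = integer(), members = list())
    class(out) <- c("region_set", class(out))
    return(out)
  }
  out <- list_rbind(regions) %>% arrange(.data$chrom, .data$start)
  # merge any overlapping spans so the region set is disjoint
  merged <- list(out[1, ])
  if (nrow(out) > 1) {
    for (i in 2:nrow(out)) {
      lastr <- merged[[length(merged)]]
      cur <- out[i, ]
      if (cur$chrom == lastr$chrom && cur$start < lastr$end) {
        lastr$end <- max(lastr$end, cur$end)
        if (cur$index_p < lastr$index_p) {
          lastr$index_snp <- cur$index_snp
          lastr$index_p <- cur$index_p
        }
        lastr$n_snps <- lastr$n_snps + cur$n_snps
        lastr$members <- list(sort(c(lastr$members[[1]], cur$members[[1]])))
        merged[[length(merged)]] <- lastr
      } else {
        merged[[length(merged) + 1]] <- cur
      }
    }
  }
  out <- list_rbind(merged) %>%
    mutate(label = sprintf("clump%02d", row_number()),
           score = -log10(.data$index_p)) %>%
    relocate("chrom", "start", "end", "label", "score")
  class(out) <- c("region_set", class(out))
  out
}

#' Validate clump regions against the clumping criteria
#'
#' Re-checks, independently of the clumping code path, that regions are
#' disjoint and that every member SNP lies inside its region, within the
#' distance window of the index SNP, and below the member P threshold.
#'
#' @param regions output of [clump()].
#' @param assoc the association results used.
#' @param p_member,window thresholds used in the clumping call.
#' @return TRUE invisibly; aborts with a message on any violation.
#' @export
validate_clumps <- function(regions, assoc, p_member = 0.01, window = 1e6) {
  if (!nrow(regions)) return(invisible(TRUE))
  by_chrom <- split(regions, regions$chrom)
  for (rc in by_chrom) {
    rc <- arrange(rc, .data$start)
    if (nrow(rc) > 1 && any(rc$start[-1] < rc$end[-nrow(rc)])) {
      abort("clump regions overlap")
    }
  }
  amap <- setNames(seq_len(nrow(assoc)), assoc$snp)
  for (i in seq_len(nrow(regions))) {
    m <- amap[regions$members[[i]]]
    ipos <- assoc$pos[amap[regions$index_snp[i]]]
    if (any(assoc$pos[m] < regions$start[i] | assoc$pos[m] >= regions$end[i]))
      abort("member SNP outside its region")
    if (any(abs(assoc$pos[m] - ipos) > window))
      abort("member SNP beyond the distance window")
    if (any(assoc$p[m] >= p_member))
      abort("member SNP above the member P threshold")
  }
  invisible(TRUE)
}

#' Map regions to genes within a flank
#'
#' Each region's gene list contains every gene whose span overlaps
#' \[start - flank, end + flank), clipped at zero. Overlap uses 0-based
#' half-open coordinates via [IRanges::findOverlaps()].
#'
#' @param regions a region tibble (`chrom`, `start`, `end`, `label`).
#' @param gene_catalog tibble `gene`, `chrom`, `start`, `end`.
#' @param flank expansion in bp on each side (default 500 kb).
#' @return A tibble with one row per (region, gene) pair: `label`, `chrom`,
#'   `start`, `end`, `gene`. Regions with no gene are kept with `gene = NA`.
#' @export
expand_regions <- function(regions, gene_catalog, flank = 5e5) {
  regions <- as_tibble(regions)
  if (!nrow(regions)) {
    return(tibble(label = character(), chrom = character(), start = numeric(),
                  end = numeric(), gene = character()))
  }
  hits <- overlap_pairs(
    tibble(chrom = regions$chrom,
           start = pmax(0, regions$start - flank),
           end = regions$end + flank),
    gene_catalog
  )
  regions %>%
    mutate(.row = row_number()) %>%
    left_join(mutate(hits, gene = gene_catalog$gene[.data$j]),
              by = c(".row" = "i")) %>%
    select("label", "chrom", "start", "end", "gene")
}

# 0-based half-open interval overlap via IRanges; returns tibble(i, j)
overlap_pairs <- function(x, y) {
  res <- list()
  for (ch in unique(x$chrom)) {
    xi <- which(x$chrom == ch)
    yi <- which(y$chrom == ch)
    if (!length(xi) || !length(yi)) next
    rx <- IRanges::IRanges(start = x$start[xi] + 1, end = x$end[xi])
    ry <- IRanges::IRanges(start = y$start[yi] + 1, end = y$end[yi])
    ov <- IRanges::findOverlaps(rx, ry)
    if (length(ov)) {
      res[[ch]] <- tibble(i = xi[S4Vectors::queryHits(ov)],
                          j = yi[S4Vectors::subjectHits(ov)])
    }
  }
  if (!length(res)) return(tibble(i = integer(), j = integer()))
  list_rbind(unname(res))
}
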