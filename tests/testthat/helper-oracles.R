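# Independent brute-force oracles and small fixture builders.
# Oracles are written in the most naive style possible (explicit loops,
# direct re-reading of the printed rules) so they share no code path with
# the implementation they check.

make_geno <- function(gt, pos = NULL, chrom = "chr1", breed = "breedX",
                      group = NULL, chip = "c1") {
  gt <- as.matrix(gt)
  n <- nrow(gt); m <- ncol(gt)
  if (is.null(pos)) pos <- seq(0, by = 1000, length.out = m)
  if (is.null(group)) group <- rep("unknown", n)
  samples <- tibble::tibble(
    sample = sprintf("s%03d", seq_len(n)),
    breed = breed, group = group, chip = chip
  )
  snps <- tibble::tibble(
    snp = sprintf("m%04d", seq_len(m)), chrom = chrom, pos = pos,
    ref = "A", alt = "B"
  )
  rownames(gt) <- samples$sample
  colnames(gt) <- snps$snp
  new_geno(gt, snps, samples)
}

# naive greedy clumping, straight from the printed rule
oracle_clump <- function(assoc, gt, p_index = 1e-4, p_member = 0.01,
                         r2_min = 0.8, window = 1e6) {
  assoc <- assoc[order(assoc$chrom, assoc$pos), ]
  taken <- rep(FALSE, nrow(assoc))
  regions <- list()
  while (TRUE) {
    best <- NA; best_p <- Inf; best_pos <- Inf
    for (i in seq_len(nrow(assoc))) {
      if (!taken[i] && assoc$p[i] < p_index) {
        if (assoc$p[i] < best_p ||
            (assoc$p[i] == best_p && assoc$pos[i] < best_pos)) {
          best <- i; best_p <- assoc$p[i]; best_pos <- assoc$pos[i]
        }
      }
    }
    if (is.na(best)) break
    members <- best
    for (i in seq_len(nrow(assoc))) {
      if (i == best || taken[i]) next
      if (assoc$chrom[i] != assoc$chrom[best]) next
      if (abs(assoc$pos[i] - assoc$pos[best]) > window) next
      if (assoc$p[i] >= p_member) next
      x <- gt[, assoc$snp[best]]; y <- gt[, assoc$snp[i]]
      ok <- !is.na(x) & !is.na(y)
      if (sum(ok) < 3 || sd(x[ok]) == 0 || sd(y[ok]) == 0) next
      if (cor(x[ok], y[ok])^2 > r2_min) members <- c(members, i)
    }
    taken[members] <- TRUE
    regions[[length(regions) + 1]] <- list(
      chrom = assoc$chrom[best],
      start = min(assoc$pos[members]),
      end = max(assoc$pos[members]) + 1,
      index_snp = assoc$snp[best],
      members = sort(assoc$snp[members])
    )
  }
  if (!length(regions)) return(regions)
  # merge overlapping spans, mirroring the documented disjointness rule
  ord <- order(sapply(regions, `[[`, "chrom"), sapply(regions, `[[`, "start"))
  regions <- regions[ord]
  merged <- list(regions[[1]])
  for (r in regions[-1]) {
    last <- merged[[length(merged)]]
    if (r$chrom == last$chrom && r$start < last$end) {
      last$end <- max(last$end, r$end)
      last$members <- sort(c(last$members, r$members))
      merged[[length(merged)]] <- last
    } else merged[[length(merged) + 1]] <- r
  }
  merged
}

# exhaustive maximal-interval enumeration for the fixation rule, followed
# by the documented representative selection within overlap clusters
# (most SNPs, then highest low-MAF fraction, then leftmost)
oracle_fixation <- function(pos, maf, min_span = 1e6, min_snps = 5,
                            maf_thresh = 0.05, min_frac = 0.95) {
  n <- length(pos)
  ok <- function(i, j) {
    m <- maf[i:j]
    (pos[j] - pos[i]) > min_span && (j - i + 1) > min_snps &&
      mean(m < maf_thresh) > min_frac
  }
  res <- list()
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i || !ok(i, j)) next
    left_ext <- i > 1 && ok(i - 1, j)
    right_ext <- j < n && ok(i, j + 1)
    if (!left_ext && !right_ext) {
      res[[length(res) + 1]] <- list(
        start = pos[i], end = pos[j] + 1, n = j - i + 1,
        frac = mean(maf[i:j] < maf_thresh)
      )
    }
  }
  if (!length(res)) return(res)
  res <- res[order(sapply(res, `[[`, "start"))]
  # split into overlap clusters
  clusters <- list(list(res[[1]]))
  hi <- res[[1]]$end
  for (r in res[-1]) {
    if (r$start < hi) {
      clusters[[length(clusters)]] <- c(clusters[[length(clusters)]], list(r))
    } else {
      clusters[[length(clusters) + 1]] <- list(r)
    }
    hi <- max(hi, r$end)
  }
  lapply(clusters, function(cl) {
    best <- cl[[1]]
    for (r in cl[-1]) {
      if (r$n > best$n ||
          (r$n == best$n && r$frac > best$frac) ||
          (r$n == best$n && r$frac == best$frac && r$start < best$start)) {
        best <- r
      }
    }
    c(start = best$start, end = best$end)
  })
}

# brute-force point-in-intervals membership
oracle_in_intervals <- function(pos, starts, ends) {
  out <- logical(length(pos))
  for (i in seq_along(pos)) {
    for (k in seq_along(starts)) {
      if (pos[i] >= starts[k] && pos[i] < ends[k]) { out[i] <- TRUE; break }
    }
  }
  out
}

# small sequencing fixture: 4 case + 4 control dogs, explicit carriers
make_variant_table <- function(positions, carriers, chrom = "chr1",
                               consequence = NULL,
                               dogs = NULL) {
  if (is.null(dogs)) {
    dogs <- tibble::tibble(
      dog = c(paste0("case", 1:4), paste0("ctrl", 1:4)),
      breed = c("B1", "B1", "B2", "B2", "B1", "B1", "B2", "B2"),
      group = rep(c("case", "control"), each = 4)
    )
  }
  m <- length(positions)
  if (is.null(consequence)) consequence <- rep("noncoding", m)
  variants <- tibble::tibble(
    variant_id = sprintf("v%03d", seq_len(m)),
    chrom = chrom, pos = positions,
    ref = "A", alt = "T", class = "SNP", consequence = consequence
  )
  calls <- purrr::map(seq_len(m), function(i) {
    tibble::tibble(variant_id = variants$variant_id[i], dog = dogs$dog,
                   gt = ifelse(dogs$dog %in% carriers[[i]], 1L, 0L))
  }) |> purrr::list_rbind()
  new_variant_table(variants, calls, dogs)
}
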