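#' Quantile-normalize intensities within each chip
#'
#' Each sample's pooled intensity values (both channels, all SNPs) are
#' replaced by rank-matched quantiles of a reference curve, so that after
#' normalization every sample has the same marginal intensity distribution
#' while within-sample rank order is preserved exactly. The reference is
#' built per chip as the rank-mean quantile curve of that chip's samples;
#' chip curves are then averaged after standardizing each to its mean, and
#' the pooled curve is rescaled to the average chip level. With a single
#' chip this reduces exactly to plain rank-mean quantile normalization
#' (two samples \[1,2,3\] and \[10,20,30\] both become \[5.5, 11, 16.5\]).
#' The scale standardization means a per-chip multiplicative gain changes
#' the normalized data only by one global factor, so downstream calling is
#' invariant to chip gain.
#'
#' @param intensities tibble with columns `sample`, `chip`, `snp`, `a`, `b`.
#' @return A tibble of the same shape and row order with `a`, `b` replaced
#'   by their normalized values.
#' @export
quantile_normalize_per_chip <- function(intensities) {
  stopifnot(all(c("sample", "chip", "snp", "a", "b") %in% names(intensities)))
  if (any(intensities$a < 0 | intensities$b < 0, na.rm = TRUE)) {
    abort("intensities must be non-negative")
  }
  chips <- unique(intensities$chip)
  chip_data <- list()
  for (ch in chips) {
    rows <- which(intensities$chip == ch)
    sub <- intensities[rows, ]
    smp <- unique(sub$sample)
    ord <- order(match(sub$sample, smp), sub$snp)
    n_per <- length(ord) / length(smp)
    if (n_per != round(n_per)) abort("unbalanced intensity table within chip")
    mat <- rbind(
      matrix(sub$a[ord], nrow = n_per, ncol = length(smp)),
      matrix(sub$b[ord], nrow = n_per, ncol = length(smp))
    )
    if (length(smp) < 2) {
      warn(paste0("chip '", ch, "' has a single sample; passed through"))
      chip_data[[ch]] <- list(rows = rows, ord = ord, n_per = n_per,
                              mat = mat, skip = TRUE)
      next
    }
    ref <- rowMeans(apply(mat, 2, sort))
    chip_data[[ch]] <- list(rows = rows, ord = ord, n_per = n_per, mat = mat,
                            ref = ref, level = mean(ref), skip = FALSE)
  }
  active <- purrr::keep(chip_data, function(cd) !cd$skip)
  out <- intensities
  if (length(active)) {
    shapes <- vapply(active, function(cd) cd$ref / cd$level,
                     numeric(length(active[[1]]$ref)))
    target <- rowMeans(as.matrix(shapes)) *
      mean(vapply(active, function(cd) cd$level, numeric(1)))
    lookup <- function(x) {
      r <- rank(x, ties.method = "average")
      (target[floor(r)] + target[ceiling(r)]) / 2
    }
    for (cd in active) {
      nm <- apply(cd$mat, 2, lookup)
      out$a[cd$rows[cd$ord]] <- as.vector(nm[seq_len(cd$n_per), ])
      out$b[cd$rows[cd$ord]] <- as.vector(nm[cd$n_per + seq_len(cd$n_per), ])
    }
  }
  out
}

#' Principal-axis coordinates of one SNP's two-channel cloud
#'
#' Centers the (A, B) cloud and rotates it to its principal axes. PC1 is
#' the genotype-contrast axis, with orientation fixed so that increasing
#' PC1 correlates with increasing A-channel intensity.
#'
#' @param x numeric matrix with two columns (A, B), one row per sample.
#' @return A list with `scores` (n x 2), `center`, `rotation` (2 x 2,
#'   columns = PC directions), `var_explained` (length 2), and `flag`
#'   (TRUE for a zero-variance cloud, in which case scores are all zero).
#' @export
snp_pca <- function(x) {
  x <- as.matrix(x)
  stopifnot(ncol(x) == 2)
  if (nrow(x) < 3) abort("snp_pca needs at least 3 samples")
  ctr <- colMeans(x)
  xc <- sweep(x, 2, ctr)
  saa <- mean(xc[, 1]^2); sbb <- mean(xc[, 2]^2); sab <- mean(xc[, 1] * xc[, 2])
  tot <- saa + sbb
  if (tot < 1e-12) {
    return(list(scores = matrix(0, nrow(x), 2), center = ctr,
                rotation = diag(2), var_explained = c(0, 0), flag = TRUE))
  }
  theta <- 0.5 * atan2(2 * sab, saa - sbb)
  v1 <- c(cos(theta), sin(theta))
  v2 <- c(-sin(theta), cos(theta))
  l1 <- saa * v1[1]^2 + 2 * sab * v1[1] * v1[2] + sbb * v1[2]^2
  l2 <- tot - l1
  if (l2 > l1) { tmp <- v1; v1 <- v2; v2 <- tmp; tmp <- l1; l1 <- l2; l2 <- tmp }
  if (sum(xc[, 1] * (xc %*% v1)) < 0) v1 <- -v1
  rot <- cbind(v1, v2)
  list(scores = xc %*% rot, center = ctr, rotation = rot,
       var_explained = c(l1, l2) / tot, flag = FALSE)
}

t_mix_logdens <- function(delta, sigma2, df) {
  lgamma((df + 2) / 2) - lgamma(df / 2) - log(df * pi) - log(sigma2) -
    ((df + 2) / 2) * log1p(delta / df)
}

#' EM fit of a t-distribution mixture to one SNP's PC coordinates
#'
#' Fits a k-component bivariate t mixture (component location, isotropic
#' scale and weight; fixed degrees of freedom) by EM using the standard
#' normal/gamma augmentation, which makes the observed-data log-likelihood
#' monotone non-decreasing. Components are initialized by a quantile split
#' along PC1 and, after convergence, ordered along PC1 (decreasing, i.e.
#' A-rich first; ties broken by weight) and mapped to genotypes 0/1/2. A
#' sample is called at the argmax posterior genotype when the maximum
#' posterior reaches the no-call threshold, otherwise missing.
#'
#' @param pc numeric matrix (n x 2) of PC coordinates.
#' @param k number of components (2 or 3).
#' @param df t degrees of freedom (> 2, fixed).
#' @param max_iter,tol EM iteration cap and relative log-likelihood
#'   convergence tolerance.
#' @param no_call posterior threshold below which a sample is set missing.
#' @param init_locations optional k x 2 matrix of starting component
#'   locations in PC space (e.g. pooled genotype anchors projected onto the
#'   SNP's principal axes). When omitted, components start from a quantile
#'   split along PC1; the quantile split can land in a poor local optimum
#'   when cluster sizes are very unbalanced, which is why the full calling
#'   pipeline supplies anchor starts.
#' @return A list with `genotype` (integer, NA = no-call), `posterior`
#'   (n x k, columns in genotype order), `confidence` (max posterior),
#'   `locations` (k x 2), `scales`, `weights`, `df`, `loglik` (trace),
#'   `converged`, `flag` (non-convergence or a twice-empty component).
#' @export
em_t_mixture_call <- function(pc, k = 3, df = 5, max_iter = 200, tol = 1e-6,
                              no_call = 0.95, init_locations = NULL) {
  if (!k %in% 2:3) abort("k must be 2 or 3")
  if (df <= 2) abort("df must exceed 2")
  pc <- as.matrix(pc)
  n <- nrow(pc)

  init <- function() {
    if (!is.null(init_locations)) {
      mu <- as.matrix(init_locations)
      stopifnot(nrow(mu) == k, ncol(mu) == 2)
      s2 <- rep(max((min(stats::dist(mu)) / 6)^2, 1e-6), k)
      return(list(mu = mu, s2 = s2, w = rep(1 / k, k)))
    }
    qs <- quantile(pc[, 1], probs = seq(0, 1, length.out = k + 1))
    grp <- cut(pc[, 1], breaks = unique(qs), include.lowest = TRUE)
    if (length(levels(grp)) < k) grp <- factor(sample.int(k, n, replace = TRUE))
    mu <- t(vapply(split(seq_len(n), grp), function(i) colMeans(pc[i, , drop = FALSE]),
                   numeric(2)))
    rownames(mu) <- NULL
    if (nrow(mu) < k) mu <- mu[rep(seq_len(nrow(mu)), length.out = k), , drop = FALSE]
    s2 <- rep(max(mean(pc^2) / k, 1e-6), k)
    list(mu = mu, s2 = s2, w = rep(1 / k, k))
  }

  run_em <- function(par) {
    mu <- par$mu; s2 <- par$s2; w <- par$w
    ll_trace <- numeric(0)
    converged <- FALSE
    empty_hits <- 0L
    for (it in seq_len(max_iter)) {
      delta <- vapply(seq_len(k), function(j) {
        rowSums(sweep(pc, 2, mu[j, ])^2) / s2[j]
      }, numeric(n))
      logf <- vapply(seq_len(k), function(j) t_mix_logdens(delta[, j], s2[j], df),
                     numeric(n))
      lw <- sweep(logf, 2, log(pmax(w, 1e-300)), "+")
      m <- apply(lw, 1, max)
      lse <- m + log(rowSums(exp(lw - m)))
      ll <- sum(lse)
      ll_trace <- c(ll_trace, ll)
      r <- exp(lw - lse)
      if (it > 1 && abs(ll - ll_trace[it - 1]) <=
          tol * (abs(ll_trace[it - 1]) + 1e-12)) {
        converged <- TRUE
        break
      }
      nk <- colSums(r)
      if (any(nk < 1e-8)) {
        empty_hits <- empty_hits + 1L
        if (empty_hits > 1L) break
        j0 <- which(nk < 1e-8)
        mu[j0, ] <- pc[sample.int(n, length(j0)), , drop = FALSE]
        s2[j0] <- max(mean(pc^2), 1e-6)
        w <- rep(1 / k, k)
        next
      }
      u <- (df + 2) / (df + delta)
      ru <- r * u
      for (j in seq_len(k)) {
        mu[j, ] <- colSums(ru[, j] * pc) / sum(ru[, j])
        s2[j] <- max(sum(ru[, j] * rowSums(sweep(pc, 2, mu[j, ])^2)) /
                       (2 * nk[j]), 1e-8)
      }
      w <- nk / n
    }
    list(mu = mu, s2 = s2, w = w, r = r, ll = ll_trace,
         converged = converged, empty = empty_hits > 1L)
  }

  fit <- run_em(init())
  flag <- !fit$converged || fit$empty
  # order along PC1, decreasing (A-rich component first -> genotype 0);
  # ties broken by weight (heavier = common homozygote first)
  ord <- order(-fit$mu[, 1], -fit$w)
  posterior <- fit$r[, ord, drop = FALSE]
  conf <- apply(posterior, 1, max)
  gcall <- max.col(posterior, ties.method = "first") - 1L
  gcall[conf < no_call] <- NA_integer_
  list(
    genotype = gcall,
    posterior = posterior,
    confidence = conf,
    locations = fit$mu[ord, , drop = FALSE],
    scales = sqrt(fit$s2[ord]),
    weights = fit$w[ord],
    df = df,
    loglik = fit$ll,
    converged = fit$converged,
    flag = flag
  )
}

#' Call genotypes from two-channel array intensities
#'
#' The full intensity-based calling pipeline: per-chip quantile
#' normalization, SNP-wise principal-component rotation, and EM clustering
#' with a t-distribution mixture. Because per-SNP centering discards the
#' absolute cluster positions, component-to-genotype assignment uses
#' genotype anchors estimated once from the pooled normalized cloud of all
#' SNPs (k-means, ordered by A-B contrast): each SNP's component locations
#' are mapped back to channel space and assigned the genotype of the
#' nearest anchor, and components landing on the same anchor pool their
#' posteriors. This keeps the ordering-along-PC1 rule for well-separated
#' three-cluster SNPs while giving monomorphic and two-cluster SNPs a
#' calibrated genotype label.
#'
#' @param intensities tibble with columns `sample`, `chip`, `snp`, `a`,
#'   `b`.
#' @param samples sample sheet tibble with columns `sample` and optionally
#'   `breed`, `group`, `chip` (chip is taken from `intensities`).
#' @param k,df,max_iter,tol,no_call see [em_t_mixture_call()].
#' @param anchor_points number of pooled points used to estimate the
#'   genotype anchors.
#' @param snp_map optional tibble with columns `snp`, `chrom`, `pos` (and
#'   optionally `ref`, `alt`) attached to the result so downstream mapping
#'   steps know SNP coordinates.
#' @return An object of class `call_set`: list with `gt` (samples x SNPs
#'   integer matrix, NA = no-call), `confidence` (same shape), `params`
#'   (per-SNP tibble: component locations, scales, weights, df,
#'   convergence and degeneracy flags, PC1 variance share), `anchors`
#'   (3 x 2), `snps`, `samples`.
#' @export
call_genotypes <- function(intensities, samples = NULL, k = 3, df = 5,
                           max_iter = 200, tol = 1e-6, no_call = 0.95,
                           anchor_points = 20000, snp_map = NULL) {
  norm <- quantile_normalize_per_chip(intensities)
  snp_ids <- sort(unique(norm$snp))
  sample_ids <- unique(norm$sample)
  if (is.null(samples)) {
    samples <- distinct(norm, .data$sample, .data$chip)
  } else {
    samples <- as_tibble(samples) %>%
      select(-dplyr::any_of("chip")) %>%
      left_join(distinct(norm, .data$sample, .data$chip), by = "sample")
    sample_ids <- samples$sample
  }
  norm <- arrange(norm, match(.data$snp, snp_ids), match(.data$sample, sample_ids))
  n_s <- length(sample_ids); n_snp <- length(snp_ids)
  if (nrow(norm) != n_s * n_snp) abort("intensity table is not complete")
  A <- matrix(norm$a, n_s, n_snp, dimnames = list(sample_ids, snp_ids))
  B <- matrix(norm$b, n_s, n_snp, dimnames = list(sample_ids, snp_ids))

  pooled <- cbind(as.vector(A), as.vector(B))
  if (nrow(pooled) > anchor_points) {
    pooled <- pooled[sample.int(nrow(pooled), anchor_points), ]
  }
  km <- stats::kmeans(pooled, centers = 3, nstart = 5, iter.max = 50)
  anchors <- km$centers[order(-(km$centers[, 1] - km$centers[, 2])), ]
  rownames(anchors) <- c("0", "1", "2")

  gt <- matrix(NA_integer_, n_s, n_snp, dimnames = list(sample_ids, snp_ids))
  conf <- matrix(NA_real_, n_s, n_snp, dimnames = list(sample_ids, snp_ids))
  params <- vector("list", n_snp)
  for (j in seq_len(n_snp)) {
    x <- cbind(A[, j], B[, j])
    pca <- snp_pca(x)
    if (pca$flag) {
      gt[, j] <- 1L  # all points coincide; genotype from nearest anchor
      ctr <- pca$center
      g0 <- which.min(colSums((t(anchors) - ctr)^2))
      gt[, j] <- as.integer(g0 - 1L)
      conf[, j] <- 1
      params[[j]] <- tibble(snp = snp_ids[j], converged = TRUE, flag = TRUE,
                            degenerate = TRUE, pc1_var = NA_real_,
                            loc = list(NULL), scales = list(NULL),
                            weights = list(NULL))
      next
    }
    anchor_pc <- sweep(anchors, 2, pca$center) %*% pca$rotation
    # standardize the cloud scale so the EM fit (and its relative-tolerance
    # stopping rule) is exactly invariant to global intensity scaling
    s0 <- sqrt(mean(pca$scores^2))
    fit <- em_t_mixture_call(pca$scores / s0, k = k, df = df,
                             max_iter = max_iter, tol = tol,
                             no_call = no_call,
                             init_locations = anchor_pc[seq_len(k), , drop = FALSE] / s0)
    fit$locations <- fit$locations * s0
    fit$scales <- fit$scales * s0
    loc_ab <- sweep(fit$locations %*% t(pca$rotation), 2, pca$center, "+")
    comp_geno <- apply(loc_ab, 1, function(p) {
      which.min(colSums((t(anchors) - p)^2)) - 1L
    })
    post_g <- matrix(0, n_s, 3)
    for (cidx in seq_len(k)) {
      gcol <- comp_geno[cidx] + 1L
      post_g[, gcol] <- post_g[, gcol] + fit$posterior[, cidx]
    }
    cj <- apply(post_g, 1, max)
    gj <- max.col(post_g, ties.method = "first") - 1L
    gj[cj < no_call] <- NA_integer_
    gt[, j] <- gj
    conf[, j] <- cj
    params[[j]] <- tibble(snp = snp_ids[j], converged = fit$converged,
                          flag = fit$flag, degenerate = FALSE,
                          pc1_var = pca$var_explained[1],
                          loc = list(fit$locations),
                          scales = list(fit$scales),
                          weights = list(fit$weights))
  }
  snps <- distinct(norm, snp = .data$snp)
  if (!is.null(snp_map)) {
    snps <- left_join(snps, as_tibble(snp_map), by = "snp")
  }
  structure(
    list(gt = gt, confidence = conf, params = list_rbind(params),
         anchors = anchors, snps = snps, samples = samples),
    class = "call_set"
  )
}

#' @export
print.call_set <- function(x, ...) {
  cat("<call_set> ", nrow(x$gt), " samples x ", ncol(x$gt), " SNPs; ",
      sprintf("call rate %.1f%%", 100 * mean(!is.na(x$gt))), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.call_set <- function(x, ...) {
  tibble(
    sample = rep(rownames(x$gt), times = ncol(x$gt)),
    snp = rep(colnames(x$gt), each = nrow(x$gt)),
    gt = as.integer(x$gt),
    confidence = as.numeric(x$confidence)
  )
}

#' @export
glance.call_set <- function(x, ...) {
  tibble(
    n_samples = nrow(x$gt),
    n_snps = ncol(x$gt),
    call_rate = mean(!is.na(x$gt)),
    n_flagged_snps = sum(x$params$flag),
    mean_confidence = mean(x$confidence, na.rm = TRUE)
  )
}

#' Concordance between called and true genotypes
#'
#' @param calls a `call_set` or integer matrix of calls.
#' @param truth integer matrix of true genotypes with the same dimensions.
#' @return A one-row tibble with `concordance` (agreement among non-missing
#'   calls), `call_rate` and `n_called`.
#' @export
genotype_concordance <- function(calls, truth) {
  gt <- if (inherits(calls, "call_set")) calls$gt else calls
  stopifnot(all(dim(gt) == dim(truth)))
  called <- !is.na(gt)
  tibble(
    concordance = mean(gt[called] == truth[called]),
    call_rate = mean(called),
    n_called = sum(called)
  )
}

#' Cohort quality-control filters
#'
#' Applies the cohort filters in a fixed order: (1) SNPs with call rate
#' at or below `min_snp_call` are removed; (2) samples with call rate at or
#' below `min_sample_call` are removed; (3) SNPs with minor allele
#' frequency at or below `min_maf` (computed after sample removal) are
#' removed. The removal report lists every removal with its reason and the
#' offending value.
#'
#' @param x a `call_set` or `geno` object.
#' @param min_snp_call SNP call-rate threshold (keep if strictly greater).
#' @param min_sample_call sample call-rate threshold (keep if strictly
#'   greater).
#' @param min_maf MAF threshold (keep if strictly greater).
#' @return A list with `geno` (filtered [new_geno()] object) and `report`
#'   (tibble `step`, `entity`, `id`, `reason`, `value`).
#' @export
qc_filter <- function(x, min_snp_call = 0.90, min_sample_call = 0.25,
                      min_maf = 0.05) {
  if (inherits(x, "call_set")) {
    snps <- x$snps
    if (!"chrom" %in% names(snps)) snps <- mutate(snps, chrom = NA_character_, pos = NA_integer_)
    g <- new_geno(x$gt, snps, x$samples)
  } else if (inherits(x, "geno")) {
    g <- x
  } else abort("x must be a call_set or geno object")
  if (!length(g$gt)) abort("empty call set")

  report <- list()
  snp_cr <- colMeans(!is.na(g$gt))
  drop_snp <- snp_cr <= min_snp_call
  if (any(drop_snp)) {
    report$snp_call <- tibble(step = 1L, entity = "snp",
                              id = colnames(g$gt)[drop_snp],
                              reason = "snp_call_rate",
                              value = snp_cr[drop_snp])
    g <- subset_geno(g, snps = !drop_snp)
  }
  smp_cr <- if (ncol(g$gt)) rowMeans(!is.na(g$gt)) else
    setNames(rep(0, nrow(g$gt)), rownames(g$gt))
  drop_smp <- smp_cr <= min_sample_call
  if (all(drop_smp)) abort("all samples removed by QC")
  if (any(drop_smp)) {
    report$sample_call <- tibble(step = 2L, entity = "sample",
                                 id = rownames(g$gt)[drop_smp],
                                 reason = "sample_call_rate",
                                 value = smp_cr[drop_smp])
    g <- subset_geno(g, samples = !drop_smp)
  }
  maf <- snp_freq(g)$maf
  drop_maf <- is.na(maf) | maf <= min_maf
  if (any(drop_maf)) {
    report$maf <- tibble(step = 3L, entity = "snp",
                         id = colnames(g$gt)[drop_maf],
                         reason = "maf", value = maf[drop_maf])
    g <- subset_geno(g, snps = !drop_maf)
  }
  report_tbl <- if (length(report)) list_rbind(unname(report)) else tibble(
    step = integer(), entity = character(), id = character(),
    reason = character(), value = numeric())
  list(geno = g, report = report_tbl)
}
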