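#' Genotype matrix container
#'
#' A light container for coded genotypes: an integer matrix of allele-B
#' dosages (0/1/2, `NA` = missing) with samples in rows and SNPs in columns,
#' plus a SNP map and a sample sheet. All analysis functions return tibbles;
#' this object only carries the one piece of the data that is not naturally
#' row-tidy.
#'
#' @param gt integer matrix, samples x SNPs, values in {0,1,2,NA}; row names
#'   are sample ids and column names SNP ids.
#' @param snps tibble with columns `snp`, `chrom`, `pos` (0-based bp) and
#'   optionally `ref`, `alt`.
#' @param samples tibble with columns `sample` and optionally `breed`,
#'   `group` (one of "case", "control", "unknown") and `chip`.
#' @return An object of class `geno`.
#' @export
new_geno <- function(gt, snps, samples) {
  gt <- as.matrix(gt)
  if (!all(gt %in% c(0L, 1L, 2L, NA), na.rm = FALSE)) {
    bad <- stats::na.omit(unique(gt[!gt %in% c(0, 1, 2) & !is.na(gt)]))
    abort(paste0("genotype codes must be 0/1/2/NA; found: ",
                 paste(utils::head(bad, 3), collapse = ", ")))
  }
  storage.mode(gt) <- "integer"
  snps <- as_tibble(snps)
  samples <- as_tibble(samples)
  stopifnot(nrow(snps) == ncol(gt), nrow(samples) == nrow(gt))
  if (is.null(rownames(gt))) rownames(gt) <- samples$sample
  if (is.null(colnames(gt))) colnames(gt) <- snps$snp
  stopifnot(nrow(gt) == 0 || identical(rownames(gt), samples$sample),
            ncol(gt) == 0 || identical(colnames(gt), snps$snp))
  structure(list(gt = gt, snps = snps, samples = samples), class = "geno")
}

#' @export
print.geno <- function(x, ...) {
  cat("<geno> ", nrow(x$gt), " samples x ", ncol(x$gt), " SNPs\n", sep = "")
  if ("group" %in% names(x$samples)) {
    tb <- table(x$samples$group)
    cat("  groups:", paste(names(tb), tb, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.geno <- function(x) dim(x$gt)

#' Long-format view of a genotype matrix
#'
#' @param x a [new_geno()] object.
#' @param ... unused.
#' @return A tibble with columns `sample`, `snp`, `gt`.
#' @export
as_tibble.geno <- function(x, ...) {
  tibble(
    sample = rep(rownames(x$gt), times = ncol(x$gt)),
    snp = rep(colnames(x$gt), each = nrow(x$gt)),
    gt = as.integer(x$gt)
  )
}

#' @export
tidy.geno <- function(x, ...) as_tibble.geno(x)

#' Subset a genotype matrix by sample and/or SNP
#'
#' @param x a `geno` object.
#' @param samples character vector of sample ids, or a logical/integer index.
#' @param snps character vector of SNP ids, or a logical/integer index.
#' @return A `geno` object.
#' @export
subset_geno <- function(x, samples = NULL, snps = NULL) {
  i <- seq_len(nrow(x$gt))
  j <- seq_len(ncol(x$gt))
  if (!is.null(samples)) {
    if (is.character(samples)) {
      i <- match(samples, rownames(x$gt))
      if (anyNA(i)) abort("unknown sample id")
    } else i <- i[samples]
  }
  if (!is.null(snps)) {
    if (is.character(snps)) {
      j <- match(snps, colnames(x$gt))
      if (anyNA(j)) abort("unknown snp id")
    } else j <- j[snps]
  }
  new_geno(x$gt[i, j, drop = FALSE], x$snps[j, , drop = FALSE],
           x$samples[i, , drop = FALSE])
}

#' Per-SNP allele-B frequency and minor allele frequency
#'
#' Frequencies are computed over non-missing genotypes.
#'
#' @param x a `geno` object.
#' @return A tibble with columns `snp`, `chrom`, `pos`, `n_called`, `af`
#'   (allele-B frequency) and `maf`.
#' @export
snp_freq <- function(x) {
  called <- colSums(!is.na(x$gt))
  af <- colSums(x$gt, na.rm = TRUE) / (2 * pmax(called, 1L))
  af[called == 0] <- NA_real_
  x$snps %>%
    select("snp", "chrom", "pos") %>%
    mutate(n_called = as.integer(called), af = af, maf = pmin(af, 1 - af))
}

#' Per-SNP and per-sample call rates
#' @param x a `geno` object.
#' @return A list with tibbles `snps` (`snp`, `call_rate`) and `samples`
#'   (`sample`, `call_rate`).
#' @export
call_rates <- function(x) {
  list(
    snps = tibble(snp = colnames(x$gt),
                  call_rate = colMeans(!is.na(x$gt))),
    samples = tibble(sample = rownames(x$gt),
                     call_rate = rowMeans(!is.na(x$gt)))
  )
}
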