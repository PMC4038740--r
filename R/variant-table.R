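#' Sequencing variant table
#'
#' Container for targeted-sequencing variants: a variant annotation tibble,
#' per-dog genotype calls in long format, and the dog sample sheet.
#'
#' @param variants tibble with columns `variant_id`, `chrom`, `pos`
#'   (0-based), `ref`, `alt`, `class` (SNP/INDEL/deletion) and
#'   `consequence`.
#' @param calls long tibble with columns `variant_id`, `dog`, `gt`
#'   (allele-B dosage 0/1/2, `NA` missing).
#' @param dogs tibble with columns `dog`, `breed`, `group`
#'   (case/control).
#' @return An object of class `variant_table`.
#' @export
new_variant_table <- function(variants, calls, dogs) {
  variants <- as_tibble(variants)
  calls <- as_tibble(calls)
  dogs <- as_tibble(dogs)
  stopifnot(all(c("variant_id", "chrom", "pos") %in% names(variants)),
            all(c("variant_id", "dog", "gt") %in% names(calls)),
            all(c("dog", "group") %in% names(dogs)))
  if (!all(calls$dog %in% dogs$dog)) abort("calls reference unknown dogs")
  if (!all(calls$variant_id %in% variants$variant_id)) {
    abort("calls reference unknown variants")
  }
  structure(list(variants = variants, calls = calls, dogs = dogs),
            class = "variant_table")
}

#' @export
print.variant_table <- function(x, ...) {
  cat("<variant_table> ", nrow(x$variants), " variants x ", nrow(x$dogs),
      " dogs\n", sep = "")
  if ("status" %in% names(x$variants)) {
    tb <- table(x$variants$status)
    cat("  status:", paste(names(tb), tb, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
as_tibble.variant_table <- function(x, ...) x$variants

#' @export
tidy.variant_table <- function(x, ...) x$variants

#' Subset a variant table by dog
#'
#' @param x a `variant_table`.
#' @param dogs character vector of dog ids to keep.
#' @return A `variant_table` restricted to those dogs; variant annotations
#'   (including any previously computed status) are reset to the raw
#'   columns, since status depends on the dog set.
#' @export
subset_dogs <- function(x, dogs) {
  keep <- x$dogs %>% filter(.data$dog %in% dogs)
  if (!nrow(keep)) abort("no dogs left after subsetting")
  raw_cols <- intersect(
    c("variant_id", "chrom", "pos", "ref", "alt", "class", "consequence",
      "constrained"),
    names(x$variants)
  )
  new_variant_table(
    variants = x$variants[, raw_cols],
    calls = filter(x$calls, .data$dog %in% keep$dog),
    dogs = keep
  )
}

#' Genotyping breed panel
#'
#' Genotypes of candidate variants in an independent panel of dogs from
#' high-risk and control breeds.
#'
#' @param gt integer matrix, dogs x variants, allele-B dosages 0/1/2 with
#'   `NA` missing; dimnames are dog and variant ids.
#' @param variants tibble with columns `variant_id`, `chrom`, `pos`.
#' @param dogs tibble with columns `dog` and `breed_class`
#'   ("risk" or "control_breed").
#' @return An object of class `breed_panel`.
#' @export
new_breed_panel <- function(gt, variants, dogs) {
  gt <- as.matrix(gt)
  storage.mode(gt) <- "integer"
  variants <- as_tibble(variants)
  dogs <- as_tibble(dogs)
  stopifnot(nrow(variants) == ncol(gt), nrow(dogs) == nrow(gt),
            all(dogs$breed_class %in% c("risk", "control_breed")))
  if (is.null(rownames(gt))) rownames(gt) <- dogs$dog
  if (is.null(colnames(gt))) colnames(gt) <- variants$variant_id
  structure(list(gt = gt, variants = variants, dogs = dogs),
            class = "breed_panel")
}

#' @export
print.breed_panel <- function(x, ...) {
  cat("<breed_panel> ", nrow(x$gt), " dogs x ", ncol(x$gt), " variants (",
      sum(x$dogs$breed_class == "risk"), " risk / ",
      sum(x$dogs$breed_class == "control_breed"), " control-breed dogs)\n",
      sep = "")
  invisible(x)
}

#' @export
as_tibble.breed_panel <- function(x, ...) {
  tibble(
    variant_id = rep(colnames(x$gt), each = nrow(x$gt)),
    dog = rep(rownames(x$gt), times = ncol(x$gt)),
    gt = as.integer(x$gt)
  ) %>% left_join(x$dogs, by = "dog")
}
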