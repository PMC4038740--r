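#' Read and write breedmap tables
#'
#' Plain-TSV readers/writers for the pipeline's tabular inputs: intensity
#' tables (`sample`, `chip`, `snp`, `a`, `b`), sample sheets (`sample`,
#' `breed`, `group`, optionally `chip`), SNP maps and wide genotype tables.
#'
#' @param path file path.
#' @name breedmap-io
NULL

#' @rdname breedmap-io
#' @export
read_intensity_tsv <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    sample = "c", chip = "c", snp = "c", a = "d", b = "d"))
}

#' @rdname breedmap-io
#' @param x table to write.
#' @export
write_intensity_tsv <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(path)
}

#' @rdname breedmap-io
#' @export
read_sample_sheet <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(.default = "c"))
}

#' @rdname breedmap-io
#' @export
write_sample_sheet <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(path)
}

#' Write genotypes as a wide TSV plus SNP map
#'
#' The genotype file has one row per sample (`sample` column then one
#' 0/1/2/NA column per SNP); the map file has columns `snp`, `chrom`,
#' `pos`, `ref`, `alt`.
#'
#' @param geno a [new_geno()] object.
#' @param path genotype TSV path; the map is written next to it with
#'   suffix `.map.tsv`.
#' @return The genotype path, invisibly.
#' @export
write_genotype_tsv <- function(geno, path) {
  wide <- as.data.frame(geno$gt)
  wide <- bind_cols(tibble(sample = rownames(geno$gt)), wide)
  readr::write_tsv(wide, path)
  readr::write_tsv(geno$snps, paste0(path, ".map.tsv"))
  readr::write_tsv(geno$samples, paste0(path, ".samples.tsv"))
  invisible(path)
}

#' Read genotypes written by [write_genotype_tsv()]
#' @param path genotype TSV path (expects `.map.tsv` and `.samples.tsv`
#'   alongside).
#' @return A [new_geno()] object.
#' @export
read_genotype_tsv <- function(path) {
  wide <- readr::read_tsv(path, col_types = readr::cols(
    sample = "c", .default = "i"))
  snps <- readr::read_tsv(paste0(path, ".map.tsv"), col_types = readr::cols(
    snp = "c", chrom = "c", pos = "d", .default = "c"))
  samples <- readr::read_tsv(paste0(path, ".samples.tsv"),
                             col_types = readr::cols(.default = "c"))
  gt <- as.matrix(wide[, -1])
  rownames(gt) <- wide$sample
  new_geno(gt, snps, samples)
}

#' Read a BED file (0-based half-open)
#'
#' @param path BED path (3+ columns; 4th column, when present, becomes
#'   `name`).
#' @return A tibble `chrom`, `start`, `end` (+ `name`).
#' @export
read_bed <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 3)) {
    abort(paste0("malformed BED line ", which(nf < 3)[1], " in ", path))
  }
  suppressWarnings({
    start <- as.numeric(vapply(parts, `[`, "", 2))
    end <- as.numeric(vapply(parts, `[`, "", 3))
  })
  if (anyNA(start) || anyNA(end)) {
    abort(paste0("malformed BED line ",
                 which(is.na(start) | is.na(end))[1], " in ", path))
  }
  out <- tibble(chrom = vapply(parts, `[`, "", 1), start = start, end = end)
  if (all(nf >= 4)) out$name <- vapply(parts, `[`, "", 4)
  out
}

#' Write intervals as BED (0-based half-open)
#'
#' @param x tibble with `chrom`, `start`, `end` and optionally a name and a
#'   score column.
#' @param path output path.
#' @param name,score column names to use for BED fields 4 and 5.
#' @return The path, invisibly.
#' @export
write_bed <- function(x, path, name = NULL, score = NULL) {
  cols <- list(x$chrom, format(x$start, scientific = FALSE, trim = TRUE),
               format(x$end, scientific = FALSE, trim = TRUE))
  if (!is.null(name)) cols <- c(cols, list(x[[name]]))
  if (!is.null(score)) cols <- c(cols, list(signif(x[[score]], 6)))
  lines <- do.call(paste, c(cols, sep = "\t"))
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read gene sets from a GMT file
#' @param path GMT path.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) fgsea::gmtPathways(path)

#' Write gene sets as GMT
#' @param sets named list of character vectors.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, "na", sets[[nm]]), collapse = "\t")
  }, character(1))
  readr::write_lines(lines, path)
  invisible(path)
}

gt_string <- function(g) {
  dplyr::case_when(is.na(g) ~ "./.", g == 0 ~ "0/0", g == 1 ~ "0/1",
                   TRUE ~ "1/1")
}

#' Write genotypes or a variant table as VCF 4.2
#'
#' Minimal plain-text VCF 4.2 with GT (and, for call sets, a GQ field
#' derived from the posterior confidence). Internal 0-based positions are
#' written 1-based.
#'
#' @param x a `geno`, `call_set` or `variant_table` object.
#' @param path output path (plain text).
#' @return The path, invisibly.
#' @export
write_vcf <- function(x, path) {
  if (inherits(x, "variant_table")) {
    v <- x$variants
    dogs <- x$dogs$dog
    gtm <- x$calls %>%
      select("variant_id", "dog", "gt") %>%
      pivot_wider(names_from = "dog", values_from = "gt") %>%
      arrange(match(.data$variant_id, v$variant_id))
    gtm <- as.matrix(gtm[, dogs, drop = FALSE])
    body <- tibble(
      chrom = v$chrom, pos = v$pos + 1, id = v$variant_id,
      ref = v$ref %||% "A", alt = v$alt %||% "B",
      info = paste0("CLASS=", v$class %||% ".", ";CSQ=",
                    v$consequence %||% ".")
    )
    fmt <- "GT"
    gcols <- apply(gtm, 2, gt_string)
    samples <- dogs
  } else {
    gt <- if (inherits(x, "call_set")) x$gt else x$gt
    snps <- x$snps
    body <- tibble(
      chrom = snps$chrom %||% ".", pos = (snps$pos %||% 0) + 1,
      id = snps$snp,
      ref = if ("ref" %in% names(snps)) snps$ref else "A",
      alt = if ("alt" %in% names(snps)) snps$alt else "B",
      info = "."
    )
    samples <- rownames(gt)
    gstr <- apply(gt, 1, gt_string)  # snps x samples after apply over rows
    if (inherits(x, "call_set")) {
      gq <- pmin(99L, as.integer(round(-10 * log10(pmax(1 - x$confidence, 1e-10)))))
      gq[is.na(gq)] <- 0L
      dim(gq) <- dim(x$confidence)
      gqstr <- apply(gq, 1, function(z) sprintf("%d", z))
      gcols <- matrix(paste(gstr, gqstr, sep = ":"), nrow = nrow(gstr),
                      dimnames = dimnames(gstr))
      fmt <- "GT:GQ"
    } else {
      gcols <- gstr
      fmt <- "GT"
    }
  }
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=breedmap",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    if (grepl("GQ", fmt))
      "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Call confidence, phred-like\">",
    "##INFO=<ID=CLASS,Number=1,Type=String,Description=\"Variant class\">",
    "##INFO=<ID=CSQ,Number=1,Type=String,Description=\"Consequence\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  gcols <- as.matrix(gcols)
  lines <- paste(
    body$chrom, format(body$pos, scientific = FALSE, trim = TRUE), body$id,
    body$ref, body$alt, ".", "PASS", body$info, fmt,
    apply(gcols, 1, paste, collapse = "\t"),
    sep = "\t"
  )
  readr::write_lines(c(header, lines), path)
  invisible(path)
}

#' Read a VCF into a genotype object
#'
#' Parses GT fields with [vcfR::read.vcfR()] into allele-B dosages;
#' positions become 0-based.
#'
#' @param path VCF path.
#' @param samples optional sample sheet to attach (joined on `sample`).
#' @return A [new_geno()] object.
#' @export
read_vcf_geno <- function(path, samples = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt_raw <- vcfR::extract.gt(v, element = "GT")
  dosage <- matrix(NA_integer_, nrow(gt_raw), ncol(gt_raw),
                   dimnames = dimnames(gt_raw))
  dosage[gt_raw %in% c("0/0", "0|0")] <- 0L
  dosage[gt_raw %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
  dosage[gt_raw %in% c("1/1", "1|1")] <- 2L
  fix <- vcfR::getFIX(v)
  snps <- tibble(
    snp = fix[, "ID"],
    chrom = fix[, "CHROM"],
    pos = as.numeric(fix[, "POS"]) - 1,
    ref = fix[, "REF"],
    alt = fix[, "ALT"]
  )
  smp <- tibble(sample = colnames(dosage))
  if (!is.null(samples)) smp <- left_join(smp, as_tibble(samples), by = "sample")
  new_geno(t(dosage), snps, smp)
}

#' Read a VCF into a variant table
#'
#' @param path VCF path (written by [write_vcf()] on a `variant_table`, or
#'   any VCF with GT).
#' @param dogs dog sample sheet (`dog`, `breed`, `group`); defaults to the
#'   VCF sample names with unknown breed/group.
#' @return A [new_variant_table()] object.
#' @export
read_vcf_variants <- function(path, dogs = NULL) {
  g <- read_vcf_geno(path)
  info <- readr::read_lines(path)
  info <- info[!startsWith(info, "#")]
  fields <- strsplit(info, "\t", fixed = TRUE)
  inf <- vapply(fields, `[`, "", 8)
  get_tag <- function(tag) {
    m <- regmatches(inf, regexpr(paste0(tag, "=[^;]+"), inf))
    out <- rep(NA_character_, length(inf))
    hit <- grepl(paste0(tag, "="), inf)
    out[hit] <- sub(paste0(tag, "="), "", m)
    out
  }
  variants <- g$snps %>%
    rename(variant_id = "snp") %>%
    mutate(class = get_tag("CLASS"), consequence = get_tag("CSQ"))
  calls <- tibble(
    variant_id = rep(colnames(g$gt), each = nrow(g$gt)),
    dog = rep(rownames(g$gt), times = ncol(g$gt)),
    gt = as.integer(g$gt)
  )
  if (is.null(dogs)) {
    dogs <- tibble(dog = rownames(g$gt), breed = "unknown", group = "unknown")
  }
  new_variant_table(variants, calls, dogs)
}

#' Write a full simulated study to disk
#'
#' Emits every pipeline input as plain text: intensity TSV, sample sheet,
#' genotype TSV + VCF, gene catalog BED, constrained-element BED, gene-set
#' GMT, sequencing variant VCF + dog sheet, breed-panel TSV, and the
#' planted-truth sidecar TSVs. Output is deterministic given the config
#' (the generator is re-run from `config$seed`).
#'
#' @param sim a [simulate_study()] result.
#' @param dir output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(f) file.path(dir, f)
  write_intensity_tsv(sim$intensities, fp("intensities.tsv"))
  write_sample_sheet(sim$geno$samples, fp("samples.tsv"))
  write_genotype_tsv(sim$geno, fp("genotypes.tsv"))
  write_vcf(sim$geno, fp("genotypes.vcf"))
  write_bed(sim$genes, fp("genes.bed"), name = "gene")
  write_bed(sim$constrained, fp("constrained.bed"), name = "element")
  write_gmt(sim$gene_sets, fp("gene_sets.gmt"))
  write_vcf(sim$variants, fp("variants.vcf"))
  write_sample_sheet(sim$variants$dogs, fp("seq_dogs.tsv"))
  panel_wide <- bind_cols(tibble(dog = rownames(sim$panel$gt)),
                          as.data.frame(sim$panel$gt))
  readr::write_tsv(panel_wide, fp("panel_genotypes.tsv"))
  write_sample_sheet(sim$panel$dogs, fp("panel_dogs.tsv"))
  tr <- sim$truth
  readr::write_tsv(tr$assoc, fp("truth_assoc.tsv"))
  readr::write_tsv(
    tibble(kind = c("fixed", "decoy", "rrv"),
           start = c(tr$fixed_region$start, tr$decoy_region$start,
                     tr$rrv_region$start),
           end = c(tr$fixed_region$end, tr$decoy_region$end,
                   tr$rrv_region$end)),
    fp("truth_regions.tsv"))
  readr::write_tsv(tr$burden$planted, fp("truth_burden.tsv"))
  readr::write_tsv(tr$burden$planted_variants, fp("truth_burden_variants.tsv"))
  readr::write_tsv(tr$panel, fp("truth_panel.tsv"))
  invisible(dir)
}
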