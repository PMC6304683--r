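#' Load a genotype panel and its population map
#'
#' Reads SNP genotypes from a VCF (v4.x, `GT` field; `|` separators mark
#' phased calls) or a PLINK text fileset (`.ped`/`.map`), together with a
#' sample-to-population map in TSV form (columns `sample_id`, `population`,
#' `role`). Variants are sorted by (chromosome, position) with a warning if
#' the input was unsorted; missing genotypes stay missing.
#'
#' @param path path to the `.vcf` file, or the `.ped`/`.map` basename (either
#'   file path or the common prefix) for `format = "plink_text"`.
#' @param format `"vcf"` or `"plink_text"`.
#' @param popmap_path path to the population map TSV.
#' @return list with elements `panel` (a [genotype_panel()]) and `popmap`
#'   (a [population_map()]). Any panel sample absent from the map is an error.
#' @export
load_panel <- function(path, format = c("vcf", "plink_text"), popmap_path) {
  format <- match.arg(format)
  panel <- switch(format,
                  vcf = read_vcf_panel(path),
                  plink_text = read_plink_panel(path))
  popmap <- read_popmap(popmap_path)
  validate_popmap(panel, popmap)
  list(panel = panel, popmap = popmap)
}

#' @rdname load_panel
#' @export
read_popmap <- function(popmap_path) {
  tab <- utils::read.table(popmap_path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("sample_id", "population")
  if (!all(need %in% names(tab)))
    stop("population map must have columns sample_id, population[, role]")
  if (is.null(tab$role)) tab$role <- "creole"
  population_map(tab$sample_id, tab$population, tab$role)
}

#' Read a VCF into a genotype panel
#'
#' Uses `VariantAnnotation` when available (the robust route for arbitrary
#' VCF); otherwise falls back to a minimal reader restricted to the
#' plain-text, GT-only dialect this package itself writes.
#' @param path VCF file path
#' @return a [genotype_panel()]
#' @export
read_vcf_panel <- function(path) {
  if (requireNamespace("VariantAnnotation", quietly = TRUE)) {
    vcf <- VariantAnnotation::readVcf(path)
    gt <- VariantAnnotation::geno(vcf)$GT
    rr <- SummarizedExperiment::rowRanges(vcf)
    variants <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(rr)),
      pos = BiocGenerics::start(rr),
      ref = as.character(rr$REF),
      alt = vapply(rr$ALT, function(a) as.character(a)[1], ""),
      stringsAsFactors = FALSE)
    samples <- colnames(gt)
  } else {
    lines <- readLines(path)
    lines <- lines[!startsWith(lines, "##")]
    hdr <- strsplit(sub("^#", "", lines[1]), "\t")[[1]]
    body <- strsplit(lines[-1], "\t")
    m <- do.call(rbind, body)
    variants <- data.frame(chrom = m[, 1], pos = as.integer(m[, 2]),
                           ref = m[, 4], alt = m[, 5],
                           stringsAsFactors = FALSE)
    samples <- hdr[-(1:9)]
    gt <- m[, -(1:9), drop = FALSE]
    gt <- sub(":.*$", "", gt)
  }
  parse_gt_matrix(gt, variants, samples)
}

# "0|1"-style GT strings -> dosage + haplotypes. Phasing is honored only if
# every non-missing call uses "|".
parse_gt_matrix <- function(gt, variants, samples) {
  a1 <- substr(gt, 1L, 1L)
  a2 <- substr(gt, 3L, 3L)
  sep <- substr(gt, 2L, 2L)
  tonum <- function(x) {
    x[x == "."] <- NA
    suppressWarnings(matrix(as.integer(x), nrow = nrow(gt)))
  }
  h1 <- tonum(a1); h2 <- tonum(a2)
  geno <- h1 + h2
  phased <- all(sep[!is.na(geno)] == "|") && length(gt) > 0
  hap <- NULL
  if (phased) {
    hap <- matrix(0L, nrow = nrow(gt), ncol = 2L * ncol(gt))
    hap[, seq(1L, ncol(hap), by = 2L)] <- h1
    hap[, seq(2L, ncol(hap), by = 2L)] <- h2
  }
  genotype_panel(variants, geno, samples = samples, hap = hap,
                 phased = phased)
}

#' Write a panel as plain-text VCF
#'
#' @param panel a [genotype_panel()]
#' @param path output path (`.vcf`, uncompressed)
#' @return `path`, invisibly
#' @export
write_vcf_panel <- function(panel, path) {
  v <- panel$variants
  sep <- if (panel$phased) "|" else "/"
  if (panel$phased) {
    h1 <- panel$hap[, seq(1L, ncol(panel$hap), by = 2L), drop = FALSE]
    h2 <- panel$hap[, seq(2L, ncol(panel$hap), by = 2L), drop = FALSE]
  } else {
    # arbitrary but consistent split of the dosage
    h1 <- pmin(panel$geno, 1L)
    h2 <- panel$geno - h1
  }
  gt <- matrix(paste0(ifelse(is.na(panel$geno), ".", h1), sep,
                      ifelse(is.na(panel$geno), ".", h2)),
               nrow = n_variants(panel))
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", panel$samples), collapse = "\t"))
  id <- if (is.null(v$id)) paste0(v$chrom, "_", v$pos) else v$id
  body <- paste(v$chrom, v$pos, id, v$ref, v$alt, ".", "PASS", ".", "GT",
                apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read PLINK text (.ped/.map) into a genotype panel
#'
#' Alleles may be ACGT or 1/2 codes; `0` marks a missing allele. The alt
#' (counted) allele at each SNP is the minor allele among the observed calls,
#' with ties broken by code order, so dosage conventions match the VCF route
#' for data round-tripped through [write_plink_panel()].
#' @param path `.ped` path, `.map` path, or their common prefix
#' @return a [genotype_panel()]
#' @export
read_plink_panel <- function(path) {
  base <- sub("\\.(ped|map)$", "", path)
  map <- utils::read.table(paste0(base, ".map"), stringsAsFactors = FALSE)
  names(map)[1:4] <- c("chrom", "id", "cm", "pos")
  ped <- utils::read.table(paste0(base, ".ped"), stringsAsFactors = FALSE,
                           colClasses = "character")
  samples <- ped[[2]]
  al <- as.matrix(ped[, -(1:6), drop = FALSE])
  if (ncol(al) != 2L * nrow(map))
    stop(".ped allele columns do not match the .map SNP count")
  m <- nrow(map)
  a1 <- t(al[, seq(1L, 2L * m, by = 2L), drop = FALSE])
  a2 <- t(al[, seq(2L, 2L * m, by = 2L), drop = FALSE])
  geno <- matrix(NA_integer_, nrow = m, ncol = length(samples))
  ref <- alt <- character(m)
  for (j in seq_len(m)) {
    x1 <- a1[j, ]; x2 <- a2[j, ]
    obs <- c(x1, x2)
    obs <- obs[obs != "0"]
    codes <- sort(unique(obs))
    if (length(codes) > 2) stop("more than two alleles at SNP ", map$id[j])
    if (length(codes) == 0) codes <- c("A", "G")
    if (length(codes) == 1) codes <- c(codes, NA)
    n2 <- sum(obs == codes[2])
    # minor allele is the counted (alt) allele
    if (!is.na(codes[2]) && n2 > length(obs) / 2) codes <- rev(codes)
    ref[j] <- codes[1]
    alt[j] <- ifelse(is.na(codes[2]), "N", codes[2])
    d <- (x1 == alt[j]) + (x2 == alt[j])
    d[x1 == "0" | x2 == "0"] <- NA
    geno[j, ] <- as.integer(d)
  }
  variants <- data.frame(chrom = as.character(map$chrom), pos = map$pos,
                         ref = ref, alt = alt, id = map$id,
                         stringsAsFactors = FALSE)
  genotype_panel(variants, geno, samples = samples)
}

#' Write a panel as PLINK text (.ped + .map)
#' @param panel a [genotype_panel()]
#' @param base output basename (files `<base>.ped` and `<base>.map`)
#' @return `base`, invisibly
#' @export
write_plink_panel <- function(panel, base) {
  v <- panel$variants
  id <- if (is.null(v$id)) paste0(v$chrom, "_", v$pos) else v$id
  utils::write.table(data.frame(v$chrom, id, 0, v$pos),
                     paste0(base, ".map"), quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  g <- panel$geno
  lines <- vapply(seq_len(n_samples(panel)), function(s) {
    d <- g[, s]
    a1 <- ifelse(is.na(d), "0", ifelse(d >= 1L, v$alt, v$ref))
    a2 <- ifelse(is.na(d), "0", ifelse(d == 2L, v$alt, v$ref))
    paste(c("FAM", panel$samples[s], "0", "0", "0", "-9",
            as.vector(rbind(a1, a2))), collapse = " ")
  }, "")
  writeLines(lines, paste0(base, ".ped"))
  invisible(base)
}

#' Write a population map TSV
#' @param popmap a [population_map()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_popmap <- function(popmap, path) {
  utils::write.table(popmap, path, quote = FALSE, sep = "\t",
                     row.names = FALSE)
  invisible(path)
}

#' Write a square distance matrix in PHYLIP format
#' @param d symmetric matrix with row/col names
#' @param path output path
#' @return `path`, invisibly
#' @export
write_phylip <- function(d, path) {
  stopifnot(nrow(d) == ncol(d))
  lines <- c(sprintf("%5d", nrow(d)),
             vapply(seq_len(nrow(d)), function(i) {
               paste(formatC(rownames(d)[i], width = -10),
                     paste(sprintf("%.6f", d[i, ]), collapse = " "))
             }, ""))
  writeLines(lines, path)
  invisible(path)
}

#' Export candidate regions as BED (0-based half-open)
#' @param regions data.frame of candidate regions (see [merge_regions()])
#' @param path output path
#' @return `path`, invisibly
#' @export
write_regions_bed <- function(regions, path) {
  bed <- data.frame(regions$chrom, regions$start - 1L, regions$end,
                    paste0(regions$method, "_", seq_len(nrow(regions))))
  utils::write.table(bed, path, quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a data frame as a TSV with a header line
#' @param x data.frame
#' @param path output path
#' @return `path`, invisibly
#' @export
write_tsv <- function(x, path) {
  is_list <- vapply(x, is.list, TRUE)
  for (j in which(is_list))   # e.g. region member lists -> comma-joined
    x[[j]] <- vapply(x[[j]], paste, "", collapse = ",")
  utils::write.table(x, path, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(path)
}
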