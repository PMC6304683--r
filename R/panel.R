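#' SNP genotype panel
#'
#' The central container of the package: an ordered set of biallelic variants
#' with per-sample alt-allele dosages and, when phased, the underlying pair of
#' binary haplotypes per sample. Variants are kept sorted by (chromosome,
#' position); coordinates are 1-based inclusive throughout the package (BED
#' exports convert to 0-based half-open).
#'
#' @param variants data.frame with columns `chrom`, `pos` (bp, 1-based),
#'   `ref`, `alt`. Extra columns are preserved.
#' @param geno integer matrix, variants in rows, samples in columns; dosage of
#'   the alt allele in `{0, 1, 2}` with `NA` for missing calls.
#' @param samples character vector of sample ids (defaults to `colnames(geno)`).
#' @param hap optional 0/1 integer matrix of haplotypes, variants in rows and
#'   `2 * n_samples` columns ordered (sample1_a, sample1_b, sample2_a, ...).
#' @param phased logical; when `TRUE`, `hap` must be supplied.
#'
#' @return An object of class `genotype_panel`.
#' @export
genotype_panel <- function(variants, geno, samples = colnames(geno),
                           hap = NULL, phased = !is.null(hap)) {
  stopifnot(is.data.frame(variants),
            all(c("chrom", "pos") %in% names(variants)))
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  if (nrow(variants) != nrow(geno))
    stop("variants and genotype matrix disagree on the variant count")
  if (is.null(samples)) samples <- paste0("S", seq_len(ncol(geno)))
  if (length(samples) != ncol(geno))
    stop("sample ids do not match the genotype matrix columns")
  if (!all(c("ref", "alt") %in% names(variants))) {
    variants$ref <- if (is.null(variants$ref)) "A" else variants$ref
    variants$alt <- if (is.null(variants$alt)) "G" else variants$alt
  }
  variants$chrom <- as.character(variants$chrom)
  variants$pos <- as.integer(variants$pos)

  # chromosome blocks keep their order of first appearance (VCF convention);
  # within a chromosome, positions must be sorted and unique
  ord <- order(match(variants$chrom, unique(variants$chrom)), variants$pos)
  if (is.unsorted(ord)) {
    warning("variants were not sorted by (chromosome, position); sorting")
    variants <- variants[ord, , drop = FALSE]
    geno <- geno[ord, , drop = FALSE]
    if (!is.null(hap)) hap <- hap[ord, , drop = FALSE]
  }
  dup <- unlist(lapply(split(variants$pos, variants$chrom),
                       function(p) duplicated(p)), use.names = FALSE)
  if (any(dup))
    stop("positions must be strictly increasing within a chromosome")

  if (phased) {
    if (is.null(hap)) stop("phased panel requires haplotypes")
    hap <- as.matrix(hap)
    storage.mode(hap) <- "integer"
    if (ncol(hap) != 2L * ncol(geno) || nrow(hap) != nrow(geno))
      stop("haplotype matrix must be variants x 2*samples")
    ds <- hap[, seq(1L, ncol(hap), by = 2L), drop = FALSE] +
      hap[, seq(2L, ncol(hap), by = 2L), drop = FALSE]
    ok <- is.na(geno) | ds == geno
    if (!all(ok, na.rm = TRUE))
      stop("dosages disagree with haplotype sums")
  }

  rownames(geno) <- NULL
  colnames(geno) <- samples
  structure(list(variants = variants, samples = as.character(samples),
                 geno = geno, hap = hap, phased = isTRUE(phased)),
            class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("genotype_panel: %d variants x %d samples (%s), %d chromosome(s)\n",
              n_variants(x), n_samples(x),
              if (x$phased) "phased" else "unphased",
              length(unique(x$variants$chrom))))
  invisible(x)
}

#' @rdname genotype_panel
#' @param x a `genotype_panel`
#' @export
n_variants <- function(x) nrow(x$variants)

#' @rdname genotype_panel
#' @export
n_samples <- function(x) length(x$samples)

#' Subset a panel by variant and/or sample index
#'
#' @param panel a `genotype_panel`
#' @param variants integer or logical index over variants (optional)
#' @param samples integer, logical or character index over samples (optional)
#' @return the subset `genotype_panel`
#' @export
subset_panel <- function(panel, variants = NULL, samples = NULL) {
  stopifnot(inherits(panel, "genotype_panel"))
  v <- if (is.null(variants)) seq_len(n_variants(panel)) else variants
  if (is.logical(v)) v <- which(v)
  s <- if (is.null(samples)) seq_len(n_samples(panel)) else samples
  if (is.character(s)) s <- match(s, panel$samples)
  if (is.logical(s)) s <- which(s)
  if (anyNA(s)) stop("unknown sample id in subset")
  hap <- NULL
  if (!is.null(panel$hap)) {
    hcols <- as.vector(rbind(2L * s - 1L, 2L * s))
    hap <- panel$hap[v, hcols, drop = FALSE]
  }
  genotype_panel(panel$variants[v, , drop = FALSE],
                 panel$geno[v, s, drop = FALSE],
                 samples = panel$samples[s],
                 hap = hap, phased = panel$phased && !is.null(hap))
}

#' Haplotype columns belonging to a set of samples
#' @keywords internal
hap_cols <- function(panel, samples) {
  s <- match(samples, panel$samples)
  if (anyNA(s)) stop("unknown sample id")
  as.vector(rbind(2L * s - 1L, 2L * s))
}

#' Population map
#'
#' Maps each sample to a population label and an analysis role. Roles follow
#' the study design this package serves: `creole` (the focal admixed
#' populations), `iberian_reference` (putative source populations used as
#' scan references/replicates), `ancestral_panel` (reference panels for local
#' ancestry) and `outgroup`.
#'
#' @param sample_id,population character vectors of equal length
#' @param role character vector (recycled) drawn from the four roles above
#' @return data.frame of class `population_map`
#' @export
population_map <- function(sample_id, population,
                           role = "creole") {
  roles <- c("creole", "iberian_reference", "ancestral_panel", "outgroup")
  role <- rep_len(as.character(role), length(sample_id))
  if (!all(role %in% roles))
    stop("role must be one of: ", paste(roles, collapse = ", "))
  if (anyDuplicated(sample_id))
    stop("duplicated sample id in population map")
  out <- data.frame(sample_id = as.character(sample_id),
                    population = as.character(population),
                    role = role, stringsAsFactors = FALSE)
  class(out) <- c("population_map", "data.frame")
  out
}

#' Check a population map against a panel
#'
#' Every panel sample must be mapped and every mapped population non-empty.
#' @param panel a `genotype_panel`
#' @param popmap a `population_map`
#' @return invisibly `TRUE`; errors otherwise
#' @export
validate_popmap <- function(panel, popmap) {
  missing <- setdiff(panel$samples, popmap$sample_id)
  if (length(missing))
    stop("sample(s) not present in the population map: ",
         paste(missing, collapse = ", "))
  counts <- table(popmap$population[popmap$sample_id %in% panel$samples])
  if (any(counts == 0)) stop("empty population in map")
  invisible(TRUE)
}

#' Samples belonging to one population
#' @param popmap a `population_map`
#' @param population population label
#' @return character vector of sample ids
#' @export
pop_samples <- function(popmap, population) {
  popmap$sample_id[popmap$population == population]
}
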