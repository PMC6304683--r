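#' Per-variant allele frequency, MAF and call rate
#'
#' Frequencies are computed over all samples pooled (the package-wide
#' convention for marker QC), excluding missing genotypes pairwise.
#' @param panel a [genotype_panel()]
#' @param samples optional subset of sample ids
#' @return numeric vector over variants
#' @export
alt_freq <- function(panel, samples = NULL) {
  g <- panel$geno
  if (!is.null(samples)) g <- g[, match(samples, panel$samples), drop = FALSE]
  rowMeans(g, na.rm = TRUE) / 2
}

#' @rdname alt_freq
#' @export
maf <- function(panel, samples = NULL) {
  p <- alt_freq(panel, samples)
  pmin(p, 1 - p)
}

#' @rdname alt_freq
#' @export
call_rate <- function(panel) {
  rowMeans(!is.na(panel$geno))
}

#' Filter variants on MAF and call rate
#'
#' Retains variants with pooled MAF strictly above `maf_min` and call rate of
#' at least `call_rate_min` (the defaults mirror the common SNP-array QC of
#' MAF > 1% and call rate >= 90%). Order is preserved and the operation is
#' idempotent.
#'
#' @param panel a [genotype_panel()]
#' @param maf_min minimum minor allele frequency (exclusive bound)
#' @param call_rate_min minimum call rate (inclusive bound)
#' @return the filtered `genotype_panel`; an error if nothing survives
#' @export
filter_variants <- function(panel, maf_min = 0.01, call_rate_min = 0.90) {
  stopifnot(maf_min >= 0, maf_min <= 1, call_rate_min >= 0, call_rate_min <= 1)
  keep <- maf(panel) > maf_min & call_rate(panel) >= call_rate_min
  keep[is.na(keep)] <- FALSE
  if (!any(keep)) stop("no variant passes the MAF/call-rate filter")
  subset_panel(panel, variants = keep)
}

#' Composite genotypic r-squared between two variants
#'
#' For unphased data this is the squared Pearson correlation of alt-allele
#' dosages (the Rogers-Huff composite estimator); for phased panels it is the
#' haplotype-frequency r-squared, i.e. the squared correlation of the two 0/1
#' haplotype vectors. Missing genotypes are excluded pairwise. The value is
#' symmetric in its arguments and invariant under allele relabeling.
#'
#' @param panel a [genotype_panel()]
#' @param i,j variant indices
#' @param samples optional subset of sample ids
#' @param use_haplotypes use the haplotype route when the panel is phased
#' @return r-squared in `[0, 1]`, or `NA` if fewer than 2 shared non-missing
#'   samples or a variant has zero variance
#' @export
composite_r2 <- function(panel, i, j, samples = NULL,
                         use_haplotypes = panel$phased) {
  if (use_haplotypes && !is.null(panel$hap)) {
    cols <- if (is.null(samples)) seq_len(ncol(panel$hap)) else
      hap_cols(panel, samples)
    x <- panel$hap[i, cols]
    y <- panel$hap[j, cols]
  } else {
    scols <- if (is.null(samples)) seq_len(n_samples(panel)) else
      match(samples, panel$samples)
    x <- panel$geno[i, scols]
    y <- panel$geno[j, scols]
  }
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2) return(NA_real_)
  x <- x[ok]; y <- y[ok]
  if (stats::var(x) == 0 || stats::var(y) == 0) return(NA_real_)
  stats::cor(x, y)^2
}

# dosage-correlation r2 for a block of variants (rows); NA-safe via
# pairwise-complete correlation
r2_block <- function(mat) {
  suppressWarnings(stats::cor(t(mat), use = "pairwise.complete.obs"))^2
}

#' Greedy windowed LD pruning
#'
#' Slides a window of `window` SNPs in steps of `step` SNPs along each
#' chromosome; within a window, pairs of retained variants are visited left
#' to right and the right member of any pair with r-squared above `r2_max`
#' is dropped (PLINK `--indep-pairwise` logic). Defaults follow the common
#' array workflow: r² > 0.1, 50-SNP window, step 10.
#'
#' @param panel a [genotype_panel()]
#' @param r2_max r-squared ceiling
#' @param window window size in SNPs
#' @param step step size in SNPs
#' @return the pruned `genotype_panel`
#' @export
ld_prune <- function(panel, r2_max = 0.1, window = 50L, step = 10L) {
  stopifnot(window >= step, step >= 1)
  keep <- rep(TRUE, n_variants(panel))
  for (chr in unique(panel$variants$chrom)) {
    idx <- which(panel$variants$chrom == chr)
    start <- 1L
    repeat {
      win <- idx[seq(start, min(start + window - 1L, length(idx)))]
      win <- win[keep[win]]
      if (length(win) >= 2) {
        r2 <- r2_block(panel$geno[win, , drop = FALSE])
        for (a in seq_len(length(win) - 1L)) {
          if (!keep[win[a]]) next
          for (b in seq((a + 1L), length(win))) {
            if (!keep[win[b]]) next
            if (!is.na(r2[a, b]) && r2[a, b] > r2_max) keep[win[b]] <- FALSE
          }
        }
      }
      if (start + window - 1L >= length(idx)) break
      start <- start + step
    }
  }
  subset_panel(panel, variants = keep)
}

#' Weir-Cockerham FST between two populations
#'
#' Computes the Weir & Cockerham (1984) per-variant variance components
#' `a` (among populations), `b` (among individuals within populations) and
#' `c` (within individuals) from genotype counts, and the multi-locus
#' estimate as the ratio of sums `sum(a) / sum(a + b + c)` - never the mean
#' of per-SNP ratios. Per-variant components are returned so window scans
#' can re-aggregate them.
#'
#' @param panel a [genotype_panel()]
#' @param popmap a [population_map()]
#' @param popA,popB population labels
#' @param variants optional variant index set (default all)
#' @return list with `fst`, and data.frame `components` (`a`, `b`, `c`)
#' @export
wc_fst <- function(panel, popmap, popA, popB, variants = NULL) {
  v <- if (is.null(variants)) seq_len(n_variants(panel)) else variants
  gA <- panel$geno[v, match(pop_samples(popmap, popA), panel$samples),
                   drop = FALSE]
  gB <- panel$geno[v, match(pop_samples(popmap, popB), panel$samples),
                   drop = FALSE]
  comp <- wc_components(list(gA, gB))
  tot <- comp$a + comp$b + comp$c
  den <- sum(tot, na.rm = TRUE)
  fst <- if (is.finite(den) && den > 0)
    sum(comp$a, na.rm = TRUE) / den else NA_real_
  list(fst = fst, components = comp)
}

# W&C (1984) components for r >= 2 populations from genotype matrices
# (variants x samples each). Returns per-variant a, b, c; NA where fewer
# than 2 populations have data.
wc_components <- function(geno_list) {
  r <- length(geno_list)
  nv <- nrow(geno_list[[1]])
  n <- sapply(geno_list, function(g) rowSums(!is.na(g)))          # nv x r
  p <- sapply(geno_list, function(g) rowMeans(g, na.rm = TRUE) / 2)
  h <- sapply(geno_list, function(g) rowMeans(g == 1L, na.rm = TRUE))
  n <- matrix(n, nrow = nv); p <- matrix(p, nrow = nv); h <- matrix(h, nrow = nv)
  ok <- rowSums(n >= 1) == r & rowSums(n) > r
  nbar <- rowSums(n) / r
  nc <- (r * nbar - rowSums(n^2) / (r * nbar)) / (r - 1)
  pbar <- rowSums(n * p) / (r * nbar)
  s2 <- rowSums(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- rowSums(n * h) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  a[!ok] <- NA; b[!ok] <- NA; cc[!ok] <- NA
  # degenerate nc (all data in one population) -> undefined
  bad <- !is.finite(a) | !is.finite(b) | !is.finite(cc)
  a[bad] <- NA; b[bad] <- NA; cc[bad] <- NA
  data.frame(a = a, b = b, c = cc)
}

#' Reynolds' genetic distance between populations
#'
#' Coancestry-based distance of Reynolds, Weir & Cockerham (1983):
#' per-locus theta is estimated from allele frequencies with the small-sample
#' correction, averaged unweighted over loci, and transformed to
#' `d = -log(1 - theta)`, clipped at zero. Populations with no data yield a
#' row of `NA`.
#'
#' @param panel a [genotype_panel()]
#' @param popmap a [population_map()]
#' @param populations labels to include (default: all in the map)
#' @return symmetric distance matrix with zero diagonal
#' @export
reynolds_distance_matrix <- function(panel, popmap,
                                     populations = unique(popmap$population)) {
  if (length(populations) < 2) stop("need at least 2 populations")
  k <- length(populations)
  freq <- lapply(populations, function(pp) {
    s <- match(pop_samples(popmap, pp), panel$samples)
    g <- panel$geno[, s, drop = FALSE]
    list(p = rowMeans(g, na.rm = TRUE) / 2, n = rowSums(!is.na(g)))
  })
  d <- matrix(0, k, k, dimnames = list(populations, populations))
  for (i in seq_len(k - 1)) for (j in seq((i + 1), k)) {
    d[i, j] <- d[j, i] <- reynolds_pair(freq[[i]], freq[[j]])
  }
  d
}

reynolds_pair <- function(fa, fb) {
  ok <- fa$n >= 1 & fb$n >= 1 & is.finite(fa$p) & is.finite(fb$p)
  if (!any(ok)) return(NA_real_)
  p1 <- fa$p[ok]; p2 <- fb$p[ok]
  n1 <- fa$n[ok]; n2 <- fb$n[ok]
  sq <- (p1 - p2)^2 + ((1 - p1) - (1 - p2))^2
  het <- n1 * (1 - p1^2 - (1 - p1)^2) + n2 * (1 - p2^2 - (1 - p2)^2)
  al <- sq / 2 - (n1 + n2) * het / (4 * n1 * n2 * (n1 + n2 - 1))
  dl <- sq / 2 + (4 * n1 * n2 - n1 - n2) * het / (4 * n1 * n2 * (n1 + n2 - 1))
  theta <- ifelse(dl > 0, al / dl, NA_real_)
  theta_bar <- mean(theta, na.rm = TRUE)
  theta_bar <- min(max(theta_bar, 0), 0.999999)
  -log(1 - theta_bar)
}

#' Classical MDS on pairwise Hamming distances
#'
#' The sample-by-sample distance is the average per-variant allele mismatch
#' (`metric = "allele"`: mean of |dosage difference| / 2, PLINK's 1 - IBS
#' flavour) or the binary genotype mismatch rate (`metric = "binary"`),
#' excluding missing calls pairwise. Coordinates come from
#' [stats::cmdscale()] and are deterministic up to axis sign.
#'
#' @param panel a [genotype_panel()]
#' @param k number of dimensions (clipped to `n_samples - 1` with a warning)
#' @param metric `"allele"` or `"binary"`
#' @return list with `coords` (samples x k), `eig_share` (per returned axis,
#'   shares of the positive eigenvalue mass; sums to <= 1) and `dist`
#' @export
hamming_mds <- function(panel, k = 20L, metric = c("allele", "binary")) {
  metric <- match.arg(metric)
  n <- n_samples(panel)
  if (k > n - 1) {
    warning("k clipped to n_samples - 1")
    k <- n - 1L
  }
  g <- panel$geno
  d <- matrix(0, n, n, dimnames = list(panel$samples, panel$samples))
  for (i in seq_len(n - 1)) for (j in seq((i + 1), n)) {
    diffs <- abs(g[, i] - g[, j])
    if (metric == "binary") diffs <- as.numeric(diffs > 0)
    else diffs <- diffs / 2
    d[i, j] <- d[j, i] <- mean(diffs, na.rm = TRUE)
  }
  mds <- stats::cmdscale(stats::as.dist(d), k = k, eig = TRUE)
  pos <- pmax(mds$eig, 0)
  share <- if (sum(pos) > 0) pos[seq_len(k)] / sum(pos) else rep(0, k)
  coords <- mds$points
  if (ncol(coords) < k) {  # cmdscale drops null axes
    coords <- cbind(coords, matrix(0, n, k - ncol(coords)))
  }
  list(coords = coords, eig_share = share, dist = d)
}
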