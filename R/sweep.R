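#' Genome-scan configuration
#'
#' Defaults reproduce the conservative array-data workflow this package
#' implements: haplotype tracking truncated at inter-marker gaps above
#' 500 kb, EHH integration cut off at 0.05, the upper 1% of standardized
#' scores called significant, SNPs validated in at least 2 of 3 reference
#' replicates, FST summarized in non-overlapping 500-kb windows anchored at
#' position 1 with outliers above the 99% quantile, at least 2 significant
#' SNPs per FST window, and FST windows required in all reference replicates.
#'
#' @param max_gap bp; haplotype tracking truncates at larger gaps
#' @param ehh_cutoff EHH level where iHH integration stops
#' @param sig_tail upper tail mass called significant (0.01 = extreme 1%)
#' @param two_sided use both tails (tail mass split equally)
#' @param min_reference_support reference replicates needed to validate a SNP
#' @param fst_window window width in bp
#' @param fst_quantile quantile defining FST outlier windows
#' @param fst_min_snps minimum significant SNPs inside an outlier window
#' @return list of class `scan_config`
#' @export
scan_config <- function(max_gap = 5e5, ehh_cutoff = 0.05, sig_tail = 0.01,
                        two_sided = FALSE, min_reference_support = 2L,
                        fst_window = 5e5, fst_quantile = 0.99,
                        fst_min_snps = 2L) {
  stopifnot(sig_tail > 0, sig_tail < 1, fst_quantile > 0, fst_quantile < 1,
            fst_window > 0, max_gap > 0)
  structure(list(max_gap = max_gap, ehh_cutoff = ehh_cutoff,
                 sig_tail = sig_tail, two_sided = two_sided,
                 min_reference_support = min_reference_support,
                 fst_window = fst_window, fst_quantile = fst_quantile,
                 fst_min_snps = fst_min_snps),
            class = "scan_config")
}

#' EHH decay curve from a core SNP
#'
#' Haplotype homozygosity extended marker by marker away from the core:
#' after refining through marker `m`, `EHH(m) = sum_h C(n_h, 2) / C(n, 2)`
#' over the distinct extended haplotypes `h`. The curve starts at 1 at the
#' core, is non-increasing with distance, and truncates at gaps larger than
#' `max_gap`.
#'
#' @param panel a phased [genotype_panel()]
#' @param core variant index (global, within the panel)
#' @param direction `+1` toward larger positions, `-1` toward smaller
#' @param samples optional sample subset
#' @param max_gap truncation gap in bp
#' @return data.frame `pos`, `ehh` (first row is the core at EHH 1)
#' @export
ehh_curve <- function(panel, core, direction = 1L, samples = NULL,
                      max_gap = 5e5) {
  if (!panel$phased || is.null(panel$hap))
    stop("EHH needs phased haplotypes; supply a phased VCF or panel")
  chr <- panel$variants$chrom[core]
  vidx <- which(panel$variants$chrom == chr)
  cols <- if (is.null(samples)) seq_len(ncol(panel$hap)) else
    hap_cols(panel, samples)
  if (length(cols) < 4) stop("need at least 4 haplotypes")
  hap <- t(panel$hap[vidx, cols, drop = FALSE])
  res <- .ehh_curve_cpp(hap, panel$variants$pos[vidx],
                        match(core, vidx), as.integer(direction), max_gap)
  data.frame(pos = res$pos, ehh = res$ehh)
}

#' Integrated EHH over one flank
#'
#' Trapezoidal integral of an EHH curve over physical distance from the core
#' outward, stopping after the first segment that drops below `cutoff` (or
#' at the curve's truncation point). Doubling all inter-marker distances
#' doubles the value; a one-point curve gives 0.
#'
#' @param curve data.frame `pos`, `ehh` as returned by [ehh_curve()]
#' @param cutoff EHH stopping level
#' @return iHH in bp x EHH units
#' @export
ihh <- function(curve, cutoff = 0.05) {
  if (nrow(curve) < 2) return(0)
  total <- 0
  for (i in 2:nrow(curve)) {
    d <- abs(curve$pos[i] - curve$pos[i - 1])
    total <- total + d * (curve$ehh[i] + curve$ehh[i - 1]) / 2
    if (curve$ehh[i] < cutoff) break
  }
  total
}

#' Cross-population EHH scan (XP-EHH)
#'
#' For every core SNP, integrates each population's EHH out to the point
#' where the pooled-sample EHH drops below the cutoff, and scores
#' `raw = ln(iHH_obs / iHH_ref)`; scores are standardized genome-wide to
#' mean 0, SD 1. Positive scores mark unusually long haplotypes in the
#' observed (Creole) population relative to the reference. Cores where
#' either iHH is 0 are dropped.
#'
#' @param obs_panel phased [genotype_panel()] of the focal population
#' @param ref_panel phased panel of the reference population (same variants)
#' @param cfg a [scan_config()]
#' @param ref_label label stored with the scores
#' @return data.frame of class `sweep_scores`: `index`, `chrom`, `pos`,
#'   `ihh_obs`, `ihh_ref`, `raw`, `z`, `ref`
#' @export
xpehh_scan <- function(obs_panel, ref_panel, cfg = scan_config(),
                       ref_label = "ref") {
  if (!obs_panel$phased || !ref_panel$phased)
    stop("XP-EHH needs phased haplotypes; supply phased VCFs")
  if (!identical(obs_panel$variants$pos, ref_panel$variants$pos) ||
      !identical(obs_panel$variants$chrom, ref_panel$variants$chrom))
    stop("panels must share the variant list")
  v <- obs_panel$variants
  rows <- list()
  for (chr in unique(v$chrom)) {
    vidx <- which(v$chrom == chr)
    if (length(vidx) < 2) next
    hA <- t(obs_panel$hap[vidx, , drop = FALSE])
    hB <- t(ref_panel$hap[vidx, , drop = FALSE])
    m <- .xpehh_pair_cpp(hA, hB, v$pos[vidx], seq_along(vidx),
                         cfg$ehh_cutoff, cfg$max_gap)
    rows[[chr]] <- data.frame(index = vidx, chrom = chr, pos = v$pos[vidx],
                              ihh_obs = m[, 1], ihh_ref = m[, 2],
                              stringsAsFactors = FALSE)
  }
  sc <- do.call(rbind, rows)
  sc <- sc[sc$ihh_obs > 0 & sc$ihh_ref > 0, , drop = FALSE]
  sc$raw <- log(sc$ihh_obs / sc$ihh_ref)
  sc$z <- (sc$raw - mean(sc$raw)) / stats::sd(sc$raw)
  sc$ref <- ref_label
  rownames(sc) <- NULL
  class(sc) <- c("sweep_scores", "data.frame")
  sc
}

#' Significant SNPs of one scan
#'
#' The upper `sig_tail` of the standardized score distribution (both tails,
#' each `sig_tail / 2`, when `two_sided`). Warns below 1000 scored SNPs.
#'
#' @param scores a `sweep_scores` data.frame
#' @param cfg a [scan_config()]
#' @return character vector of significant SNP keys (`chrom:pos`)
#' @export
significant_snps <- function(scores, cfg = scan_config()) {
  if (nrow(scores) < 1000)
    warning("fewer than 1000 scored SNPs; tail quantiles are unstable")
  key <- paste0(scores$chrom, ":", scores$pos)
  if (cfg$two_sided) {
    lo <- stats::quantile(scores$z, cfg$sig_tail / 2, names = FALSE)
    hi <- stats::quantile(scores$z, 1 - cfg$sig_tail / 2, names = FALSE)
    key[scores$z > hi | scores$z < lo]
  } else {
    hi <- stats::quantile(scores$z, 1 - cfg$sig_tail, names = FALSE)
    key[scores$z > hi]
  }
}

#' Validate significant SNPs across reference replicates
#'
#' @param sets list of significant-SNP key vectors, one per reference
#' @param min_support minimum number of sets a SNP must appear in
#' @return character vector of validated keys
#' @export
validate_replicates <- function(sets, min_support = 2L) {
  if (length(sets) < 2) stop("need at least 2 reference sets")
  tab <- table(unlist(lapply(sets, unique)))
  names(tab)[tab >= min_support]
}

#' Merge significant SNPs into candidate regions
#'
#' Within each chromosome, runs of significant SNPs are merged, allowing at
#' most one non-significant SNP between consecutive significant members;
#' isolated significant SNPs (runs of size 1) are discarded. Each region is
#' extended by half the physical distance to the neighbouring
#' non-significant marker on both sides (clipped at the chromosome's first
#' position when there is no outer marker). Output regions are disjoint and
#' sorted.
#'
#' @param validated character keys (`chrom:pos`) of validated SNPs
#' @param scored data.frame with `chrom`, `pos` of every scored SNP
#' @param method label stored on the regions
#' @param cluster optional label of the focal cluster/breed
#' @return data.frame of class `candidate_regions`: `chrom`, `start`, `end`,
#'   `length_kbp`, `n_snps`, `method`, `cluster`, plus a list column
#'   `members` holding each region's significant SNP keys (the input for
#'   ancestry-deviation scoring)
#' @export
merge_regions <- function(validated, scored, method = "XP-EHH",
                          cluster = NA_character_) {
  out <- list()
  for (chr in unique(scored$chrom)) {
    pos <- sort(scored$pos[scored$chrom == chr])
    sig <- paste0(chr, ":", pos) %in% validated
    sidx <- which(sig)
    if (length(sidx) < 2) next
    runs <- list(); cur <- sidx[1]
    for (k in sidx[-1]) {
      gap_snps <- k - cur[length(cur)] - 1L   # non-significant SNPs between
      if (gap_snps <= 1L) cur <- c(cur, k)
      else { runs[[length(runs) + 1L]] <- cur; cur <- k }
    }
    runs[[length(runs) + 1L]] <- cur
    for (r in runs) {
      if (length(r) < 2) next                 # isolated SNPs are discarded
      first <- r[1]; last <- r[length(r)]
      start <- if (first > 1)
        pos[first] - (pos[first] - pos[first - 1]) / 2 else pos[first]
      end <- if (last < length(pos))
        pos[last] + (pos[last + 1] - pos[last]) / 2 else pos[last]
      start <- max(1, start)
      row <- data.frame(
        chrom = chr, start = floor(start), end = floor(end),
        n_snps = length(r), method = method, cluster = cluster,
        stringsAsFactors = FALSE)
      row$members <- list(paste0(chr, ":", pos[r]))
      out[[length(out) + 1L]] <- row
    }
  }
  if (!length(out))
    return(structure(data.frame(chrom = character(), start = numeric(),
                                end = numeric(), length_kbp = numeric(),
                                n_snps = integer(), method = character(),
                                cluster = character()),
                     class = c("candidate_regions", "data.frame")))
  reg <- do.call(rbind, out)
  reg$length_kbp <- region_length_kbp(reg$start, reg$end)
  reg <- reg[order(reg$chrom, reg$start),
             c("chrom", "start", "end", "length_kbp", "n_snps", "method",
               "cluster", "members")]
  rownames(reg) <- NULL
  class(reg) <- c("candidate_regions", "data.frame")
  reg
}

#' Region length in kbp
#'
#' `(end - start) / 1000`, rounded half-up to one decimal (printing
#' convention for candidate-region tables).
#' @param start,end 1-based inclusive bounds
#' @return length in kbp
#' @export
region_length_kbp <- function(start, end) {
  stopifnot(all(end >= start))
  floor((end - start) / 100 + 0.5) / 10
}

#' Windowed FST scan with replicate validation
#'
#' Weir-Cockerham FST of the focal population against each reference, as a
#' ratio of component sums inside non-overlapping windows anchored at
#' position 1 (`[k*w + 1, (k+1)*w]`). A window is an outlier when it exceeds
#' the per-comparison empirical `fst_quantile` in every reference
#' comparison and holds at least `fst_min_snps` significant SNPs.
#' Significant SNPs default to the top `sig_tail` of per-SNP FST (averaged
#' over comparisons); pass the validated XP-EHH set via `sig_snps` to use the
#' companion haplotype scan instead.
#'
#' @param panel a [genotype_panel()] holding focal and reference samples
#' @param popmap a [population_map()]
#' @param focal_pop focal population label
#' @param ref_pops reference population labels (replicates)
#' @param cfg a [scan_config()]
#' @param sig_snps optional character keys (`chrom:pos`) of significant SNPs
#' @return list: `windows` (per window, FST per comparison), `outliers`
#'   (a `candidate_regions` data.frame, method `"FST"`)
#' @export
fst_window_scan <- function(panel, popmap, focal_pop, ref_pops,
                            cfg = scan_config(), sig_snps = NULL) {
  v <- panel$variants
  win_id <- paste0(v$chrom, ":", (v$pos - 1) %/% cfg$fst_window)
  comps <- lapply(ref_pops, function(rp) {
    gA <- panel$geno[, match(pop_samples(popmap, focal_pop), panel$samples),
                     drop = FALSE]
    gB <- panel$geno[, match(pop_samples(popmap, rp), panel$samples),
                     drop = FALSE]
    wc_components(list(gA, gB))
  })
  names(comps) <- ref_pops

  uw <- unique(win_id)
  wtab <- data.frame(
    win = uw,
    chrom = sub(":.*$", "", uw),
    k = as.numeric(sub("^.*:", "", uw)),
    stringsAsFactors = FALSE)
  wtab$start <- wtab$k * cfg$fst_window + 1
  wtab$end <- (wtab$k + 1) * cfg$fst_window
  wtab$n_snps <- as.integer(table(win_id)[wtab$win])

  is_outlier <- matrix(FALSE, nrow(wtab), length(ref_pops))
  for (j in seq_along(ref_pops)) {
    comp <- comps[[j]]
    num <- tapply(comp$a, win_id, sum, na.rm = TRUE)[wtab$win]
    den <- tapply(comp$a + comp$b + comp$c, win_id, sum, na.rm = TRUE)[wtab$win]
    fst <- ifelse(den > 0, num / den, NA)
    wtab[[paste0("fst_", ref_pops[j])]] <- as.numeric(fst)
    thr <- stats::quantile(fst, cfg$fst_quantile, na.rm = TRUE, names = FALSE)
    is_outlier[, j] <- !is.na(fst) & fst > thr
  }

  if (is.null(sig_snps)) {
    snp_fst <- rowMeans(sapply(comps, function(cp) {
      tot <- cp$a + cp$b + cp$c
      ifelse(!is.na(tot) & tot > 0, cp$a / tot, NA)
    }), na.rm = TRUE)
    thr <- stats::quantile(snp_fst, 1 - cfg$sig_tail, na.rm = TRUE,
                           names = FALSE)
    sig_snps <- paste0(v$chrom, ":", v$pos)[!is.na(snp_fst) & snp_fst > thr]
  }
  key <- paste0(v$chrom, ":", v$pos)
  nsig <- tapply(key %in% sig_snps, win_id, sum)[wtab$win]

  ok <- rowSums(is_outlier) == length(ref_pops) & nsig >= cfg$fst_min_snps
  outliers <- wtab[ok, c("chrom", "start", "end", "n_snps"), drop = FALSE]
  if (nrow(outliers)) {
    outliers$length_kbp <- region_length_kbp(outliers$start, outliers$end)
    outliers$method <- "FST"
    outliers <- outliers[order(outliers$chrom, outliers$start),
                         c("chrom", "start", "end", "length_kbp", "n_snps",
                           "method")]
  } else {
    outliers <- data.frame(chrom = character(), start = numeric(),
                           end = numeric(), length_kbp = numeric(),
                           n_snps = integer(), method = character())
  }
  rownames(outliers) <- NULL
  class(outliers) <- c("candidate_regions", "data.frame")
  list(windows = wtab[order(wtab$chrom, wtab$start), ], outliers = outliers)
}
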