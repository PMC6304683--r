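#' Build an ancestry model from reference panels
#'
#' Per-ancestry, per-variant allele frequencies estimated from the ancestral
#' reference panels with a pseudocount of 0.5 per allele class (so no
#' frequency sits exactly at 0 or 1), plus the genome-wide mixing proportions
#' `alpha` (normalized to sum to 1) and the number of generations since
#' admixture began.
#'
#' @param ancestral named list of [genotype_panel()]s sharing a variant list
#' @param alpha named mixing proportions (default: the four-way taurine /
#'   indicine mix 0.76 Iberia, 0.12 commercial, 0.03 Africa, 0.09 zebu)
#' @param g generations since admixture (default 83)
#' @param generation_length_years calendar conversion, informational
#' @return list of class `ancestry_model`: `labels`, `freq` (variants x
#'   ancestries), `alpha`, `g`, `variants`
#' @export
build_ancestry_model <- function(ancestral,
                                 alpha = c(Iberia = 0.76, commercial = 0.12,
                                           Africa = 0.03, zebu = 0.09),
                                 g = 83, generation_length_years = 5) {
  labels <- names(ancestral)
  if (is.null(labels)) stop("ancestral panels must be named")
  if (!all(labels %in% names(alpha)))
    stop("missing ancestry panel or proportion for: ",
         paste(setdiff(labels, names(alpha)), collapse = ", "))
  v <- ancestral[[1]]$variants
  for (a in labels[-1])
    if (!identical(ancestral[[a]]$variants$pos, v$pos))
      stop("ancestral panels must share the variant list")
  for (a in labels)
    if (n_samples(ancestral[[a]]) < 5)
      warning("fewer than 5 individuals in ancestral panel ", a)
  freq <- sapply(labels, function(a) {
    g_ <- ancestral[[a]]$geno
    alt <- rowSums(g_, na.rm = TRUE)
    m <- 2 * rowSums(!is.na(g_))
    (alt + 0.5) / (m + 1)
  })
  alpha <- alpha[labels]
  alpha <- alpha / sum(alpha)
  structure(list(labels = labels, freq = freq, alpha = alpha, g = g,
                 generation_length_years = generation_length_years,
                 variants = v),
            class = "ancestry_model")
}

# one haplotype-chain forward-backward over a chromosome block.
# hapmat: markers x H (0/1 alleles); freq: markers x K; stay[m]: probability
# of no ancestry switch between marker m-1 and m. Returns H x K x M posterior
# as a list of M matrices summed into `acc` by the caller.
fb_chain <- function(hapmat, freq, alpha, stay) {
  M <- nrow(hapmat); H <- ncol(hapmat); K <- length(alpha)
  post <- array(0, c(M, H, K))
  emis <- function(m) {
    # H x K emission matrix for marker m
    a <- hapmat[m, ]
    e <- matrix(rep(freq[m, ], each = H), H, K)
    e[a == 0, ] <- 1 - e[a == 0, , drop = FALSE]
    e[is.na(a), ] <- 1            # missing allele: uninformative
    e
  }
  f <- matrix(rep(alpha, each = H), H, K) * emis(1)
  f <- f / rowSums(f)
  if (M == 1) { post[1, , ] <- f; return(post) }
  fs <- array(0, c(M, H, K)); fs[1, , ] <- f
  for (m in 2:M) {
    e <- stay[m]
    f <- (e * f + (1 - e) * matrix(rep(alpha, each = H), H, K)) * emis(m)
    f <- f / rowSums(f)
    fs[m, , ] <- f
  }
  b <- matrix(1, H, K)
  post[M, , ] <- fs[M, , ]
  for (m in (M - 1):1) {
    eb <- emis(m + 1) * b
    e <- stay[m + 1]
    b <- e * eb + (1 - e) * matrix(rep(as.vector(eb %*% alpha), K), H, K)
    b <- b / rowSums(b)
    p <- matrix(fs[m, , ], H, K) * b
    post[m, , ] <- p / rowSums(p)
  }
  post
}

#' Local ancestry by hidden Markov model
#'
#' A per-haplotype Markov chain over the ancestry labels: initial
#' distribution `alpha`, probability `1 - exp(-g * r * d)` of re-drawing the
#' ancestry from `alpha` between markers `d` bp apart (`r` = recombination
#' rate per bp), and the ancestral allele frequency as emission. Posterior
#' ancestry dosages come from the forward-backward algorithm; for unphased
#' panels the genotype is split into two pseudo-haplotypes (an approximation,
#' exact for homozygotes). At every genotyped variant the dosages over
#' ancestries sum to 2.
#'
#' @param panel admixed [genotype_panel()]; its variant list must be a
#'   subset of the model's (absent variants are skipped with a message)
#' @param model an [build_ancestry_model()] result
#' @param recomb_rate recombination rate per bp (default 1e-8)
#' @return list of class `ancestry_dosage`: `dosage` (array variants x
#'   samples x ancestries), `labels`, `variants`, `samples`
#' @export
local_ancestry <- function(panel, model, recomb_rate = 1e-8) {
  key_p <- paste0(panel$variants$chrom, ":", panel$variants$pos)
  key_m <- paste0(model$variants$chrom, ":", model$variants$pos)
  hit <- match(key_p, key_m)
  if (anyNA(hit)) {
    message(sum(is.na(hit)), " variant(s) absent from the ancestry model; skipped")
  }
  vkeep <- which(!is.na(hit))
  midx <- hit[vkeep]
  K <- length(model$labels)
  ns <- n_samples(panel)
  dosage <- array(0, c(length(vkeep), ns, K),
                  dimnames = list(NULL, panel$samples, model$labels))
  if (panel$phased && !is.null(panel$hap)) {
    h1 <- panel$hap[vkeep, seq(1, 2 * ns, 2), drop = FALSE]
    h2 <- panel$hap[vkeep, seq(2, 2 * ns, 2), drop = FALSE]
  } else {
    g <- panel$geno[vkeep, , drop = FALSE]
    h1 <- pmin(g, 1L)
    h2 <- g - h1
  }
  chrom <- panel$variants$chrom[vkeep]
  pos <- panel$variants$pos[vkeep]
  hard <- matrix(NA_integer_, length(vkeep), 2L * ns)
  for (chr in unique(chrom)) {
    rows <- which(chrom == chr)
    if (length(rows) < 2) {
      stay <- 1
    } else {
      stay <- c(1, exp(-model$g * recomb_rate * diff(pos[rows])))
    }
    fr <- model$freq[midx[rows], , drop = FALSE]
    for (half in 1:2) {
      hm <- if (half == 1) h1[rows, , drop = FALSE] else h2[rows, , drop = FALSE]
      post <- fb_chain(hm, fr, model$alpha, stay)
      dosage[rows, , ] <- dosage[rows, , , drop = FALSE] + post
      hard[rows, seq(half, 2L * ns, 2L)] <-
        apply(post, c(1, 2), which.max)
    }
  }
  structure(list(dosage = dosage, labels = model$labels,
                 variants = panel$variants[vkeep, , drop = FALSE],
                 samples = panel$samples,
                 hard_calls = hard, phased_input = panel$phased),
            class = "ancestry_dosage")
}

#' Genome-wide ancestry proportions per breed
#'
#' Per breed, the mean (over samples) of each sample's genome-wide mean
#' ancestry fraction (dosage / 2), with its SD over samples; the overall
#' `Mean` row is the unweighted mean of breed means (and the SD of breed
#' means).
#'
#' @param dos an [local_ancestry()] result, or a plain matrix of per-sample
#'   ancestry fractions (samples x ancestries)
#' @param grouping character/factor of breed labels, one per sample
#' @return data.frame: one row per breed plus a final `Mean` row; columns
#'   `<ancestry>` and `<ancestry>_sd`
#' @export
global_proportions <- function(dos, grouping) {
  frac <- if (inherits(dos, "ancestry_dosage")) {
    t(apply(dos$dosage, 2, function(m) colMeans(m) / 2))
  } else as.matrix(dos)
  if (nrow(frac) != length(grouping))
    stop("grouping must have one label per sample")
  breeds <- unique(as.character(grouping))
  per <- t(sapply(breeds, function(b)
    colMeans(frac[grouping == b, , drop = FALSE])))
  sds <- t(sapply(breeds, function(b)
    apply(frac[grouping == b, , drop = FALSE], 2, stats::sd)))
  out <- data.frame(breed = breeds, per, check.names = FALSE)
  mean_row <- colMeans(per)
  out <- rbind(out, data.frame(breed = "Mean", t(mean_row),
                               check.names = FALSE))
  sd_block <- rbind(sds, t(apply(per, 2, stats::sd)))
  colnames(sd_block) <- paste0(colnames(per), "_sd")
  cbind(out, sd_block)
}

#' Ancestry excess/deficiency at candidate regions
#'
#' For each region, `DeltaA_k` is the mean ancestry-k fraction over the
#' region's member significant SNPs (per-SNP fractions averaged over
#' samples first) minus the genome-wide mean; deviations sum to zero over
#' ancestries. A deviation is flagged `strong` when it exceeds two
#' genome-wide SDs, the SD taken over the genome-wide per-SNP mean ancestry
#' fractions.
#'
#' @param dos an [local_ancestry()] result
#' @param region_variants list (one entry per region) of member SNP keys
#'   (`chrom:pos`) or variant indices into `dos$variants`
#' @param region_names optional region labels
#' @return data.frame: per region and ancestry, `delta` and `strong`; the
#'   genome-wide mean and SD per ancestry are attached as attributes
#'   `genome_mean`, `genome_sd`
#' @export
region_deviation <- function(dos, region_variants, region_names = NULL) {
  stopifnot(inherits(dos, "ancestry_dosage"))
  fsnp <- apply(dos$dosage, c(1, 3), mean) / 2   # variants x ancestries
  gmean <- colMeans(fsnp)
  gsd <- apply(fsnp, 2, stats::sd)
  key <- paste0(dos$variants$chrom, ":", dos$variants$pos)
  rows <- lapply(seq_along(region_variants), function(i) {
    rv <- region_variants[[i]]
    idx <- if (is.numeric(rv)) rv else match(rv, key)
    idx <- idx[!is.na(idx)]
    if (!length(idx)) stop("region ", i, " has no member variant with dosages")
    delta <- colMeans(fsnp[idx, , drop = FALSE]) - gmean
    data.frame(region = if (is.null(region_names)) paste0("R", i)
               else region_names[i],
               ancestry = dos$labels, delta = as.numeric(delta),
               strong = abs(delta) > 2 * gsd,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "genome_mean") <- gmean
  attr(out, "genome_sd") <- gsd
  out
}
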