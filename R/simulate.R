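#' Simulate a SNP panel under a demographic scenario
#'
#' Draws `n_loci` unlinked biallelic loci under the standard backward-in-time
#' structured coalescent for the given scenario and parameter values. Each
#' locus is an independent gene tree; a single mutation is applied with
#' probability `1 - exp(-mu * L)` (total tree length `L`), so loci may come
#' out monomorphic. Haplotypes are returned phased, paired into diploids.
#' Loci are laid out round-robin over `n_chrom` nominal autosomes purely for
#' bookkeeping - they are simulated without linkage either way (panels with
#' real LD come from [simulate_ld_panel()]).
#'
#' @param spec a [scenario_spec()]
#' @param params named parameter vector (see [prior_table()])
#' @param samples_per_pop named integer vector: diploids sampled per
#'   population (unnamed populations get 0)
#' @param n_loci number of loci
#' @param seed RNG seed (`NULL` for current state)
#' @param growth_steps see [scenario_events()]
#' @param n_chrom nominal autosome count for coordinates
#' @return list with `panel` (a phased [genotype_panel()]), `popmap`, and
#'   `tmrca` (per-locus tree height, generations)
#' @export
simulate_scenario <- function(spec, params, samples_per_pop, n_loci,
                              seed = NULL, growth_steps = 12L, n_chrom = 29L) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n_loci >= 1)
  built <- scenario_events(spec, params, growth_steps)
  pops <- built$populations
  nh <- integer(length(pops))
  names(nh) <- pops
  nh[names(samples_per_pop)] <- 2L * as.integer(samples_per_pop)
  mu <- as.numeric(params[["mutation_rate"]])
  sim <- .sim_coalescent_cpp(unname(nh), unname(built$pop_sizes),
                             built$events, n_loci, mu, TRUE)
  haps <- sim$haplotypes
  sampled <- pops[nh > 0]
  sample_ids <- unlist(lapply(sampled, function(p)
    paste0(p, "_", seq_len(nh[p] / 2))))
  pop_of <- unlist(lapply(sampled, function(p) rep(p, nh[p] / 2)))
  geno <- haps[, seq(1, ncol(haps), 2), drop = FALSE] +
    haps[, seq(2, ncol(haps), 2), drop = FALSE]
  chrom <- rep_len(seq_len(n_chrom), n_loci)
  pos <- integer(n_loci)
  for (cc in seq_len(n_chrom)) {
    idx <- which(chrom == cc)
    pos[idx] <- seq_len(length(idx)) * 1000000L
  }
  ord <- order(chrom, pos)
  variants <- data.frame(chrom = as.character(chrom[ord]), pos = pos[ord],
                         ref = "A", alt = "G", stringsAsFactors = FALSE)
  panel <- genotype_panel(variants, geno[ord, , drop = FALSE],
                          samples = sample_ids,
                          hap = haps[ord, , drop = FALSE], phased = TRUE)
  popmap <- population_map(sample_ids, pop_of,
                           ifelse(pop_of == "Iber", "iberian_reference",
                                  "creole"))
  list(panel = panel, popmap = popmap, tmrca = sim$tmrca)
}

#' Fast path: per-population derived-allele counts under a scenario
#'
#' Same model as [simulate_scenario()] but skips panel construction and
#' returns only, per locus, the derived allele count in each sampled
#' population - all that the ABC summary statistics need. Used to build
#' large simulation archives cheaply.
#'
#' @inheritParams simulate_scenario
#' @return list: `counts` (loci x populations), `n_hap` (haplotypes per
#'   population), `populations`
#' @export
simulate_scenario_counts <- function(spec, params, samples_per_pop, n_loci,
                                     seed = NULL, growth_steps = 12L) {
  if (!is.null(seed)) set.seed(seed)
  built <- scenario_events(spec, params, growth_steps)
  pops <- built$populations
  nh <- integer(length(pops)); names(nh) <- pops
  nh[names(samples_per_pop)] <- 2L * as.integer(samples_per_pop)
  sim <- .sim_coalescent_cpp(unname(nh), unname(built$pop_sizes),
                             built$events, n_loci,
                             as.numeric(params[["mutation_rate"]]), FALSE)
  keep <- nh > 0
  counts <- sim$counts[, keep, drop = FALSE]
  colnames(counts) <- pops[keep]
  list(counts = counts, n_hap = nh[keep], populations = pops[keep])
}

#' Forward Wright-Fisher panel with recombination
#'
#' Complements the unlinked-locus coalescent: a discrete-generation diploid
#' Wright-Fisher population with Poisson crossovers on a linear genetic map,
#' initialized at linkage equilibrium, so the simulated panel carries the LD
#' structure that the Ne-trajectory and haplotype-scan modules consume.
#' After `length(n_per_gen)` generations, `n_sample` diploids are drawn
#' (without replacement) and returned as a phased panel.
#'
#' @param n_per_gen integer vector of diploid population sizes, one entry per
#'   generation (e.g. `rep(500, 300)` for constant size)
#' @param n_chrom number of chromosomes
#' @param snps_per_chrom markers per chromosome
#' @param chrom_length_bp chromosome length
#' @param cm_per_mb linear map density (default 1 cM/Mb)
#' @param founder_maf range of founder allele frequencies, drawn uniformly
#' @param n_sample diploids to sample at the end
#' @param population label used for sample ids
#' @param mut_rate per-site per-gamete flip rate (default 0)
#' @param seed RNG seed
#' @return list with `panel` (phased) and `popmap`
#' @export
simulate_ld_panel <- function(n_per_gen, n_chrom = 20L, snps_per_chrom = 100L,
                              chrom_length_bp = 1e7, cm_per_mb = 1,
                              founder_maf = c(0.1, 0.5), n_sample = 50L,
                              population = "POP", mut_rate = 0,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  M <- n_chrom * snps_per_chrom
  chrom <- rep(seq_len(n_chrom), each = snps_per_chrom)
  pos <- rep(round(seq(1, chrom_length_bp, length.out = snps_per_chrom)),
             n_chrom)
  morgans <- pos * cm_per_mb / 1e8
  N0 <- n_per_gen[1]
  p0 <- stats::runif(M, founder_maf[1], founder_maf[2])
  founders <- matrix(stats::rbinom(2L * N0 * M, 1L, rep(p0, each = 2L * N0)),
                     nrow = 2L * N0)
  final <- .sim_wf_cpp(founders, morgans, chrom,
                       as.integer(n_per_gen), mut_rate)
  Nf <- nrow(final) / 2L
  n_sample <- min(n_sample, Nf)
  pick <- sort(sample.int(Nf, n_sample))
  hcols <- as.vector(rbind(2L * pick - 1L, 2L * pick))
  hap <- t(final[hcols, , drop = FALSE])
  geno <- hap[, seq(1, ncol(hap), 2), drop = FALSE] +
    hap[, seq(2, ncol(hap), 2), drop = FALSE]
  ids <- paste0(population, "_", seq_len(n_sample))
  variants <- data.frame(chrom = as.character(chrom), pos = pos,
                         ref = "A", alt = "G", stringsAsFactors = FALSE)
  panel <- genotype_panel(variants, geno, samples = ids, hap = hap,
                          phased = TRUE)
  list(panel = panel,
       popmap = population_map(ids, population))
}

#' Split one pool of haplotypes into diverged daughter panels
#'
#' Takes the final haplotype pool of a forward simulation, copies it into
#' `length(n_gens)` daughter populations, evolves each independently (drift +
#' recombination) for its own number of generations at its own size, and
#' returns one phased panel per daughter. The shared ancestral pool makes the
#' daughters' divergence (FST) controllable through `n_gens` and sizes.
#'
#' @param ancestor result of [simulate_ld_panel()] run with a large
#'   `n_sample` (its full phased panel seeds each daughter)
#' @param labels daughter population labels
#' @param n_gens generations of independent drift per daughter (recycled)
#' @param n_dip diploid size per daughter (recycled)
#' @param n_sample diploids sampled per daughter (recycled)
#' @param seed RNG seed
#' @return list of per-daughter lists (`panel`, `popmap`), named by label
#' @export
split_populations <- function(ancestor, labels, n_gens, n_dip, n_sample,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_gens <- rep_len(n_gens, length(labels))
  n_dip <- rep_len(n_dip, length(labels))
  n_sample <- rep_len(n_sample, length(labels))
  src <- ancestor$panel
  v <- src$variants
  morgans <- v$pos / 1e8
  chrom <- as.integer(factor(v$chrom, levels = unique(v$chrom)))
  pool <- t(src$hap)  # haplotypes x markers
  out <- list()
  for (i in seq_along(labels)) {
    Nd <- n_dip[i]
    hidx <- sample.int(nrow(pool), 2L * Nd, replace = nrow(pool) < 2L * Nd)
    founders <- pool[hidx, , drop = FALSE]
    final <- .sim_wf_cpp(founders, morgans, chrom,
                         rep(as.integer(Nd), n_gens[i]), 0)
    pick <- sort(sample.int(Nd, min(n_sample[i], Nd)))
    hcols <- as.vector(rbind(2L * pick - 1L, 2L * pick))
    hap <- t(final[hcols, , drop = FALSE])
    geno <- hap[, seq(1, ncol(hap), 2), drop = FALSE] +
      hap[, seq(2, ncol(hap), 2), drop = FALSE]
    ids <- paste0(labels[i], "_", seq_along(pick))
    out[[labels[i]]] <- list(
      panel = genotype_panel(v, geno, samples = ids, hap = hap,
                             phased = TRUE),
      popmap = population_map(ids, labels[i]))
  }
  out
}

#' Merge panels that share a variant list
#' @param panels list of phased [genotype_panel()]s over identical variants
#' @param popmaps matching list of [population_map()]s
#' @return list(panel, popmap)
#' @export
bind_panels <- function(panels, popmaps) {
  v <- panels[[1]]$variants
  for (p in panels[-1])
    if (!identical(p$variants$pos, v$pos) ||
        !identical(p$variants$chrom, v$chrom))
      stop("panels must share the variant list")
  geno <- do.call(cbind, lapply(panels, function(p) p$geno))
  phased <- all(vapply(panels, function(p) p$phased, TRUE))
  hap <- if (phased) do.call(cbind, lapply(panels, function(p) p$hap))
  samples <- unlist(lapply(panels, function(p) p$samples))
  pm <- do.call(rbind, popmaps)
  class(pm) <- c("population_map", "data.frame")
  list(panel = genotype_panel(v, geno, samples = samples, hap = hap,
                              phased = phased),
       popmap = pm)
}

#' Simulate admixed genomes with recorded ancestry tracks
#'
#' Builds each admixed haplotype as a mosaic of the ancestral reference
#' panels: ancestry tracks are drawn from an exponential track-length process
#' with mean `1 / (g * r)` bp (g generations since admixture, r recombination
#' rate per bp), the ancestry of each track sampled from `proportions`, and
#' the alleles copied from one random donor haplotype of that ancestry.
#' Truth tracks tile every chromosome without overlap and exactly explain
#' the admixed alleles.
#'
#' @param ancestral named list of phased [genotype_panel()]s sharing a
#'   variant list, one per ancestry
#' @param proportions named numeric mixing proportions (must sum to 1)
#' @param g generations since admixture (default 83)
#' @param recomb_rate per-bp recombination rate (default 1e-8)
#' @param n_samples admixed diploids to generate
#' @param seed RNG seed
#' @param population label for the admixed samples
#' @return list: `panel` (phased), `popmap`, `truth` (data.frame: sample,
#'   haplotype, chrom, start, end, ancestry)
#' @export
generate_admixed <- function(ancestral, proportions, g = 83,
                             recomb_rate = 1e-8, n_samples, seed = NULL,
                             population = "ADMIX") {
  if (!is.null(seed)) set.seed(seed)
  if (abs(sum(proportions) - 1) > 1e-8) stop("proportions must sum to 1")
  anc <- names(ancestral)
  if (is.null(anc) || !all(names(proportions) %in% anc))
    stop("ancestral panels and proportions must share names")
  for (a in anc)
    if (n_samples(ancestral[[a]]) == 0 || is.null(ancestral[[a]]$hap))
      stop("empty or unphased ancestral panel: ", a)
  v <- ancestral[[1]]$variants
  for (a in anc[-1])
    if (!identical(ancestral[[a]]$variants$pos, v$pos))
      stop("ancestral panels must share the variant list")
  pvec <- proportions[anc]
  pvec[is.na(pvec)] <- 0
  chroms <- unique(v$chrom)
  chrom_end <- vapply(chroms, function(cc) max(v$pos[v$chrom == cc]), 0)
  mean_len <- 1 / (g * recomb_rate)

  M <- nrow(v)
  hap <- matrix(0L, M, 2L * n_samples)
  tr_sample <- tr_hap <- integer(0)
  tr_chrom <- tr_anc <- character(0)
  tr_start <- tr_end <- numeric(0)
  vidx_by_chrom <- lapply(chroms, function(cc) which(v$chrom == cc))
  for (s in seq_len(n_samples)) for (h in 1:2) {
    col <- 2L * (s - 1L) + h
    for (ci in seq_along(chroms)) {
      vidx <- vidx_by_chrom[[ci]]
      pos <- v$pos[vidx]
      # draw track boundaries for the whole chromosome at once
      lens <- stats::rexp(ceiling(chrom_end[ci] / mean_len * 3) + 10,
                          rate = 1 / mean_len)
      while (sum(lens) < chrom_end[ci])
        lens <- c(lens, stats::rexp(10, rate = 1 / mean_len))
      ends <- cumsum(lens + 1)
      ntr <- which(ends >= chrom_end[ci])[1]
      ends <- pmin(ends[seq_len(ntr)], chrom_end[ci])
      starts <- c(1, utils::head(ends, -1) + 1)
      ancs <- sample(anc, ntr, replace = TRUE, prob = pvec)
      for (k in seq_len(ntr)) {
        src <- ancestral[[ancs[k]]]$hap
        donor <- sample.int(ncol(src), 1)
        inside <- vidx[pos >= starts[k] & pos <= ends[k]]
        if (length(inside))
          hap[inside, col] <- src[inside, donor]
      }
      tr_sample <- c(tr_sample, rep.int(s, ntr))
      tr_hap <- c(tr_hap, rep.int(h, ntr))
      tr_chrom <- c(tr_chrom, rep.int(chroms[ci], ntr))
      tr_start <- c(tr_start, starts)
      tr_end <- c(tr_end, ends)
      tr_anc <- c(tr_anc, ancs)
    }
  }
  truth <- data.frame(sample = tr_sample, haplotype = tr_hap,
                      chrom = tr_chrom, start = tr_start, end = tr_end,
                      ancestry = tr_anc, stringsAsFactors = FALSE)
  geno <- hap[, seq(1, ncol(hap), 2), drop = FALSE] +
    hap[, seq(2, ncol(hap), 2), drop = FALSE]
  ids <- paste0(population, "_", seq_len(n_samples))
  panel <- genotype_panel(v, geno, samples = ids, hap = hap, phased = TRUE)
  truth$sample <- ids[truth$sample]
  list(panel = panel, popmap = population_map(ids, population),
       truth = truth)
}

#' Plant a hard selective sweep into a population
#'
#' Copies one donor haplotype of the target population over an interval
#' around a core variant into a fraction `f` of that population's haplotypes;
#' the per-side extent of each carrier's copied interval is exponential with
#' mean `decay_bp`, emulating the decaying haplotype sharing of a recent
#' sweep. Other populations are untouched.
#'
#' @param panel a phased [genotype_panel()]
#' @param popmap a [population_map()]
#' @param population target population label
#' @param core variant index of the sweep core
#' @param f carrier fraction in `(0, 1]` (`f = 0` returns the panel unchanged)
#' @param decay_bp mean one-sided extent of the copied interval
#' @param seed RNG seed
#' @return list: `panel`, `core` (index), `carriers` (haplotype columns)
#' @export
plant_sweep <- function(panel, popmap, population, core, f, decay_bp,
                        seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(f >= 0, f <= 1)
  if (f == 0) return(list(panel = panel, core = core, carriers = integer()))
  if (is.null(panel$hap)) stop("plant_sweep needs a phased panel")
  cols <- hap_cols(panel, pop_samples(popmap, population))
  donor <- sample(cols, 1)
  ncarr <- max(1L, round(f * length(cols)))
  carriers <- sample(cols, ncarr)
  v <- panel$variants
  cc <- v$chrom[core]
  vidx <- which(v$chrom == cc)
  pos <- v$pos[vidx]
  hap <- panel$hap
  for (h in carriers) {
    left <- stats::rexp(1, 1 / decay_bp)
    right <- stats::rexp(1, 1 / decay_bp)
    inside <- vidx[pos >= v$pos[core] - left & pos <= v$pos[core] + right]
    hap[inside, h] <- panel$hap[inside, donor]
  }
  geno <- hap[, seq(1, ncol(hap), 2), drop = FALSE] +
    hap[, seq(2, ncol(hap), 2), drop = FALSE]
  out <- genotype_panel(v, geno, samples = panel$samples, hap = hap,
                        phased = TRUE)
  list(panel = out, core = core, carriers = carriers)
}

#' SNP-array-like ascertainment
#'
#' Uniform subsample of `n_target` variants among those with pooled MAF of at
#' least `maf_min`, preserving order - a minimal stand-in for array design
#' (common-variant enrichment without population-specific discovery bias).
#'
#' @param panel a [genotype_panel()]
#' @param maf_min MAF floor applied before subsampling
#' @param n_target variants to keep (all retained, with a warning, if fewer
#'   pass the floor)
#' @param seed RNG seed
#' @return the ascertained `genotype_panel`
#' @export
ascertain_snps <- function(panel, maf_min, n_target, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ok <- which(maf(panel) >= maf_min)
  if (length(ok) < n_target) {
    warning("fewer polymorphic variants than n_target; keeping all")
    keep <- ok
  } else {
    keep <- sort(sample(ok, n_target))
  }
  subset_panel(panel, variants = keep)
}
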