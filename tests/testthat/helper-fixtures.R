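# shared fixture builders; everything is generated in code at test time

# deterministic little panel: 5 variants x 3 samples, with one missing call
toy_panel <- function() {
  v <- data.frame(chrom = c("1", "1", "1", "2", "2"),
                  pos = c(100L, 200L, 300L, 150L, 250L),
                  ref = "A", alt = "G", stringsAsFactors = FALSE)
  geno <- matrix(c(0L, 1L, 2L,
                   1L, 1L, 0L,
                   2L, 2L, 2L,
                   0L, NA, 1L,
                   1L, 0L, 0L), nrow = 5, byrow = TRUE)
  genotype_panel(v, geno, samples = c("s1", "s2", "s3"))
}

toy_popmap <- function() {
  population_map(c("s1", "s2", "s3"), c("A", "A", "B"),
                 c("creole", "creole", "iberian_reference"))
}

# random unphased panel with given dims
random_panel <- function(n_var = 50, n_samp = 20, n_chrom = 2, seed = 1) {
  set.seed(seed)
  chrom <- as.character(rep(seq_len(n_chrom), length.out = n_var))
  chrom <- sort(chrom)
  pos <- unlist(lapply(table(chrom), function(k) sort(sample.int(1e6, k))))
  p <- runif(n_var, 0.1, 0.9)
  geno <- matrix(rbinom(n_var * n_samp, 2, rep(p, n_samp)), n_var, n_samp)
  genotype_panel(data.frame(chrom = chrom, pos = pos, ref = "A", alt = "C",
                            stringsAsFactors = FALSE),
                 geno, samples = paste0("s", seq_len(n_samp)))
}

# Balding-Nichols ancestral panels (no LD inside panels; divergence F)
# default chromosome length gives ~75-kb marker spacing, the density of the
# filtered ~33k-SNP bovine array data this generator emulates
bn_panels <- function(F = 0.2, n_chrom = 10, snps = 300, n_dip = 30,
                      labels = c("Iberia", "commercial", "Africa", "zebu"),
                      chrom_len = snps * 7.5e4, seed = 1) {
  set.seed(seed)
  M <- n_chrom * snps
  chrom <- as.character(rep(seq_len(n_chrom), each = snps))
  pos <- as.integer(rep(round(seq(1e5, chrom_len, length.out = snps)), n_chrom))
  panc <- runif(M, 0.1, 0.9)
  v <- data.frame(chrom = chrom, pos = pos, ref = "A", alt = "G",
                  stringsAsFactors = FALSE)
  out <- list()
  for (lab in labels) {
    pk <- rbeta(M, panc * (1 - F) / F, (1 - panc) * (1 - F) / F)
    hap <- matrix(rbinom(M * 2 * n_dip, 1, rep(pk, 2 * n_dip)), M, 2 * n_dip)
    geno <- hap[, seq(1, 2 * n_dip, 2)] + hap[, seq(2, 2 * n_dip, 2)]
    out[[lab]] <- genotype_panel(v, geno,
                                 samples = paste0(lab, "_", seq_len(n_dip)),
                                 hap = hap, phased = TRUE)
  }
  out
}

# forward-WF world for haplotype scans: one ancestor split into a focal
# population and three reference replicates
sweep_world <- function(seed, n_chrom = 20, snps_per_chrom = 150,
                        anc_n = 800, anc_gens = 250, split_gens = 25,
                        daughter_n = 200, n_sample = 25) {
  anc <- simulate_ld_panel(rep(anc_n, anc_gens), n_chrom = n_chrom,
                           snps_per_chrom = snps_per_chrom,
                           n_sample = anc_n, seed = seed)
  split_populations(anc, c("CRE", "IB1", "IB2", "LID"),
                    n_gens = split_gens, n_dip = daughter_n,
                    n_sample = n_sample, seed = seed + 1)
}

# truth ancestry label (index into labels) per variant for one haplotype
truth_ancestry_at <- function(truth, labels, variants, sample_id, hapl) {
  out <- integer(nrow(variants))
  tr <- truth[truth$sample == sample_id & truth$haplotype == hapl, ]
  for (i in seq_len(nrow(tr))) {
    hit <- variants$chrom == tr$chrom[i] &
      variants$pos >= tr$start[i] & variants$pos <= tr$end[i]
    out[hit] <- match(tr$ancestry[i], labels)
  }
  out
}
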