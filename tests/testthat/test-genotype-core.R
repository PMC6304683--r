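test_that("panel construction enforces the core invariants", {
  p <- toy_panel()
  expect_equal(n_variants(p), 5)
  expect_equal(n_samples(p), 3)
  # unsorted input is sorted with a warning
  v <- p$variants[c(2, 1, 3, 4, 5), ]
  expect_warning(q <- genotype_panel(v, p$geno[c(2, 1, 3, 4, 5), ]),
                 "sorted")
  expect_equal(q$variants$pos, p$variants$pos)
  # duplicated position is an error
  v2 <- p$variants; v2$pos[2] <- 100L
  expect_error(genotype_panel(v2, p$geno), "strictly increasing")
  # dosage/haplotype consistency is checked
  hap <- matrix(0L, 5, 6)
  expect_error(genotype_panel(p$variants, p$geno, hap = hap, phased = TRUE),
               "disagree")
})

test_that("load_panel round-trips VCF and PLINK text with a popmap", {
  dir <- withr::local_tempdir()
  sim <- simulate_ld_panel(rep(60L, 20), n_chrom = 2, snps_per_chrom = 20,
                           n_sample = 6, seed = 42)
  vcf <- file.path(dir, "panel.vcf")
  write_vcf_panel(sim$panel, vcf)
  pmfile <- file.path(dir, "popmap.tsv")
  write_popmap(sim$popmap, pmfile)

  got <- load_panel(vcf, "vcf", pmfile)
  expect_equal(got$panel$geno, sim$panel$geno, ignore_attr = TRUE)
  expect_true(got$panel$phased)
  expect_equal(got$panel$hap, sim$panel$hap, ignore_attr = TRUE)
  expect_equal(got$panel$variants$pos, sim$panel$variants$pos)

  # same data through the PLINK text dialect gives the identical dosages
  # (alt alleles are written as the minor allele so codings agree)
  base <- file.path(dir, "panel")
  flip <- alt_freq(sim$panel) > 0.5
  canon <- sim$panel
  canon$geno[flip, ] <- 2L - canon$geno[flip, ]
  canon <- genotype_panel(canon$variants, canon$geno, samples = canon$samples)
  write_plink_panel(canon, base)
  got2 <- read_plink_panel(base)
  expect_equal(got2$geno, canon$geno, ignore_attr = TRUE)

  # unmapped sample is a hard error naming the sample
  bad <- population_map("nobody", "X")
  bp <- file.path(dir, "bad.tsv"); write_popmap(bad, bp)
  expect_error(load_panel(vcf, "vcf", bp), "POP_1")
})

test_that("filter_variants applies MAF/call-rate rules and is idempotent", {
  set.seed(7)
  # 10 variants, 3 planted failures: monomorphic, low call rate, rare
  n <- 20L
  geno <- matrix(rbinom(10 * n, 2, 0.4), 10, n)
  geno[3, ] <- 0L                                   # MAF 0
  geno[6, sample.int(n, 3)] <- NA                   # call rate 0.85
  geno[9, ] <- c(1L, rep(0L, n - 1))                # MAF 0.025 < 0.05
  v <- data.frame(chrom = "1", pos = seq_len(10) * 100L, ref = "A", alt = "G")
  p <- genotype_panel(v, geno, samples = paste0("s", 1:n))
  f <- filter_variants(p, maf_min = 0.05, call_rate_min = 0.9)
  expect_equal(n_variants(f), 7)
  expect_false(any(f$variants$pos %in% c(300L, 600L, 900L)))
  # boundary: call rate just below the threshold is removed
  geno2 <- geno[1:2, ]; geno2[2, 1:2] <- NA         # 18/20 = 0.9 retained
  p2 <- genotype_panel(v[1:2, ], geno2, samples = paste0("s", 1:n))
  expect_equal(n_variants(filter_variants(p2, 0.05, 0.9)), 2)
  geno2[2, 3] <- NA                                 # 17/20 = 0.85 removed
  p3 <- genotype_panel(v[1:2, ], geno2, samples = paste0("s", 1:n))
  expect_equal(n_variants(filter_variants(p3, 0.05, 0.9)), 1)
  # idempotence
  expect_equal(filter_variants(f, 0.05, 0.9)$variants, f$variants)
  # nothing surviving is an error
  expect_error(filter_variants(p, maf_min = 0.99), "no variant")
})

test_that("composite_r2 matches direct evaluation and its invariances", {
  v <- data.frame(chrom = "1", pos = c(10L, 20L), ref = "A", alt = "G")
  g <- rbind(c(0L, 1L, 2L, 0L, 1L, 2L), c(0L, 1L, 2L, 0L, 1L, 0L))
  p <- genotype_panel(v, g, samples = paste0("s", 1:6))
  expect_equal(composite_r2(p, 1, 1), 1)
  # frozen from the independent oracle: cor(x, y)^2 on the stated dosages
  expect_equal(composite_r2(p, 1, 2), cor(g[1, ], g[2, ])^2)
  expect_equal(composite_r2(p, 1, 2), 0.3, tolerance = 1e-12)
  # symmetry and allele-relabeling invariance (d -> 2 - d)
  expect_equal(composite_r2(p, 1, 2), composite_r2(p, 2, 1))
  g2 <- g; g2[2, ] <- 2L - g2[2, ]
  p2 <- genotype_panel(v, g2, samples = paste0("s", 1:6))
  expect_equal(composite_r2(p2, 1, 2), composite_r2(p, 1, 2))
  # orthogonal centered dosage vectors give 0
  g3 <- rbind(c(0L, 2L, 0L, 2L), c(0L, 2L, 2L, 0L))
  p3 <- genotype_panel(v, g3, samples = paste0("s", 1:4))
  expect_equal(composite_r2(p3, 1, 2), 0)
  # zero variance is NA
  g4 <- rbind(c(1L, 1L, 1L, 1L), c(0L, 1L, 2L, 0L))
  p4 <- genotype_panel(v, g4, samples = paste0("s", 1:4))
  expect_true(is.na(composite_r2(p4, 1, 2)))
})

test_that("ld_prune removes high-LD pairs under the greedy windowed rule", {
  set.seed(11)
  base <- random_panel(n_var = 45, n_samp = 40, n_chrom = 1, seed = 11)
  # plant 5 perfect-LD duplicates (50 SNPs total)
  dup_of <- c(3L, 10L, 17L, 24L, 31L)
  v <- base$variants
  geno <- base$geno
  for (k in seq_along(dup_of)) {
    geno <- rbind(geno, geno[dup_of[k], ])
    v <- rbind(v, data.frame(chrom = "1", pos = v$pos[dup_of[k]] + 1L,
                             ref = "A", alt = "C"))
  }
  p <- suppressWarnings(genotype_panel(v, geno, samples = base$samples))
  pruned <- ld_prune(p, r2_max = 0.99, window = 50, step = 10)
  # exhaustive pairwise oracle: exactly the 5 planted duplicates must go
  expect_equal(n_variants(pruned), 45)
  r2 <- suppressWarnings(cor(t(pruned$geno))^2)
  diag(r2) <- 0
  expect_lt(max(r2, na.rm = TRUE), 0.999)
  # all-independent panel is unchanged
  ind <- random_panel(n_var = 20, n_samp = 200, n_chrom = 1, seed = 12)
  expect_equal(n_variants(ld_prune(ind, r2_max = 0.9)), 20)
})

test_that("wc_fst matches the Weir-Cockerham formula oracle", {
  # brute-force oracle for one variant, two populations, from genotype counts
  wc_oracle <- function(gA, gB) {
    r <- 2
    n <- c(sum(!is.na(gA)), sum(!is.na(gB)))
    pp <- c(mean(gA, na.rm = TRUE) / 2, mean(gB, na.rm = TRUE) / 2)
    h <- c(mean(gA == 1, na.rm = TRUE), mean(gB == 1, na.rm = TRUE))
    nbar <- mean(n)
    nc <- (sum(n) - sum(n^2) / sum(n)) / (r - 1)
    pbar <- sum(n * pp) / sum(n)
    s2 <- sum(n * (pp - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(n * h) / sum(n)
    a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) /
                          (nbar - 1))
    b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - s2 * (r - 1) / r -
                                  hbar * (2 * nbar - 1) / (4 * nbar))
    cc <- hbar / 2
    c(a = a, b = b, c = cc)
  }
  # counts table: n_A = n_B = 20, p_A = 0.8, p_B = 0.3 (HWE-ish genotypes)
  gA <- c(rep(2L, 13), rep(1L, 6), rep(0L, 1))   # p = 0.8
  gB <- c(rep(2L, 2), rep(1L, 8), rep(0L, 10))   # p = 0.3
  v <- data.frame(chrom = "1", pos = 1:1 * 10L, ref = "A", alt = "G")
  p <- genotype_panel(v, matrix(c(gA, gB), nrow = 1),
                      samples = paste0("s", 1:40))
  pm <- population_map(paste0("s", 1:40), rep(c("A", "B"), each = 20))
  got <- wc_fst(p, pm, "A", "B")
  ora <- wc_oracle(gA, gB)
  expect_equal(unlist(got$components), ora, ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_equal(got$fst, ora["a"] / sum(ora), ignore_attr = TRUE)

  # no differentiation: p_A = p_B = 0.5 at many loci, |FST| small
  set.seed(20)
  g <- matrix(rbinom(50 * 200, 2, 0.5), 50, 200)
  p2 <- genotype_panel(data.frame(chrom = "1", pos = seq_len(50) * 10L,
                                  ref = "A", alt = "G"), g,
                       samples = paste0("s", 1:200))
  pm2 <- population_map(paste0("s", 1:200), rep(c("A", "B"), each = 100))
  expect_lt(abs(wc_fst(p2, pm2, "A", "B")$fst), 0.02)

  # fixed difference approaches 1 with growing n
  g3 <- matrix(c(rep(2L, 100), rep(0L, 100)), nrow = 1)
  p3 <- genotype_panel(v, g3, samples = paste0("s", 1:200))
  expect_gt(wc_fst(p3, pm2, "A", "B")$fst, 0.99)
})

test_that("windowed FST is the ratio of sums, not a mean of ratios", {
  # fixture where the two aggregations differ: one strongly differentiated
  # variant with large components, one weak variant
  set.seed(3)
  gA <- rbind(c(rep(2L, 18), rep(1L, 2)), rbinom(20, 2, 0.5))
  gB <- rbind(c(rep(0L, 18), rep(1L, 2)), rbinom(20, 2, 0.5))
  v <- data.frame(chrom = "1", pos = c(10L, 20L), ref = "A", alt = "G")
  p <- genotype_panel(v, cbind(gA, gB), samples = paste0("s", 1:40))
  pm <- population_map(paste0("s", 1:40), rep(c("A", "B"), each = 20))
  got <- wc_fst(p, pm, "A", "B")
  comp <- got$components
  ratio_of_sums <- sum(comp$a) / sum(comp$a + comp$b + comp$c)
  mean_of_ratios <- mean(comp$a / (comp$a + comp$b + comp$c))
  expect_equal(got$fst, ratio_of_sums)
  expect_gt(abs(ratio_of_sums - mean_of_ratios), 0.01)
})

test_that("Reynolds distances behave on identical, symmetric and star fixtures", {
  set.seed(4)
  p <- random_panel(n_var = 200, n_samp = 30, seed = 4)
  pm <- population_map(p$samples, rep(c("A", "B", "C"), each = 10))
  d <- reynolds_distance_matrix(p, pm)
  expect_equal(diag(d), c(A = 0, B = 0, C = 0))
  expect_equal(d, t(d))
  expect_true(all(d >= 0))
  # identical allele frequencies: duplicate population gives 0
  p2 <- genotype_panel(p$variants, cbind(p$geno[, 1:10], p$geno[, 1:10]),
                       samples = paste0("s", 1:20))
  pm2 <- population_map(p2$samples, rep(c("A", "B"), each = 10))
  expect_equal(reynolds_distance_matrix(p2, pm2)["A", "B"], 0)

  # star phylogeny: C diverged (long branch), A and B close
  sim <- simulate_ld_panel(rep(200L, 50), n_chrom = 5, snps_per_chrom = 60,
                           n_sample = 200, seed = 5)
  pops <- split_populations(sim, c("A", "B", "C"), n_gens = c(5, 5, 60),
                            n_dip = 100, n_sample = 20, seed = 6)
  w <- bind_panels(lapply(pops, `[[`, "panel"), lapply(pops, `[[`, "popmap"))
  dd <- reynolds_distance_matrix(w$panel, w$popmap)
  expect_gt(dd["A", "C"], dd["A", "B"])
  expect_gt(dd["B", "C"], dd["A", "B"])
})

test_that("hamming MDS separates diverged groups and is near-Euclidean", {
  # two identical samples land on identical coordinates
  p <- toy_panel()
  p2 <- genotype_panel(p$variants, cbind(p$geno, p$geno[, 1]),
                       samples = c(p$samples, "s1b"))
  m <- hamming_mds(p2, k = 2)
  expect_lt(sum((m$coords["s1", ] - m$coords["s1b", ])^2), 1e-12)

  # three pairwise-equidistant samples form an equilateral triangle
  v <- data.frame(chrom = "1", pos = (1:6) * 10L, ref = "A", alt = "G")
  g <- cbind(c(2L, 2L, 0L, 0L, 0L, 0L),
             c(0L, 0L, 2L, 2L, 0L, 0L),
             c(0L, 0L, 0L, 0L, 2L, 2L))
  p3 <- genotype_panel(v, g, samples = c("a", "b", "c"))
  m3 <- hamming_mds(p3, k = 2)
  side <- dist(m3$coords)
  expect_equal(max(side), min(side), tolerance = 1e-8)

  # two diverged populations: axis 1 separates them, eig share 1 > share 2
  sim <- simulate_ld_panel(rep(200L, 30), n_chrom = 4, snps_per_chrom = 50,
                           n_sample = 200, seed = 8)
  pops <- split_populations(sim, c("A", "B"), n_gens = 40, n_dip = 80,
                            n_sample = 15, seed = 9)
  w <- bind_panels(lapply(pops, `[[`, "panel"), lapply(pops, `[[`, "popmap"))
  mm <- hamming_mds(w$panel, k = 3)
  grp <- rep(c(1, 2), each = 15)
  expect_true(all(sign(mm$coords[grp == 1, 1]) != sign(mm$coords[grp == 2, 1])))
  expect_gt(mm$eig_share[1], mm$eig_share[2])
  expect_lte(sum(mm$eig_share), 1)

  # k too large is clipped with a warning
  expect_warning(hamming_mds(p3, k = 10), "clipped")

  # near-Euclidean reconstruction from k = n - 1 coordinates
  r <- random_panel(n_var = 300, n_samp = 12, seed = 10)
  mr <- hamming_mds(r, k = 11)
  rec <- as.matrix(dist(mr$coords))
  err <- norm(rec - mr$dist, "F") / norm(mr$dist, "F")
  expect_lt(err, 0.05)
})
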