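test_that("prior draws respect ranges, ordering and reproducibility", {
  pri <- prior_table()
  d <- sample_priors(pri, 500, seed = 1)
  expect_true(all(d$Ne_ANC >= 100 & d$Ne_ANC <= 5000))
  expect_true(all(d$t1 < d$t2 & d$t2 < d$t3))
  expect_true(all(d$mutation_rate >= 1e-4 & d$mutation_rate <= 0.05))
  # reproducible from seed
  expect_identical(sample_priors(pri, 50, seed = 9),
                   sample_priors(pri, 50, seed = 9))
  # degenerate range collapses to a constant
  pri2 <- pri; pri2$min[pri2$param == "Ne_ANC"] <- 777
  pri2$max[pri2$param == "Ne_ANC"] <- 777
  expect_true(all(sample_priors(pri2, 20, seed = 2)$Ne_ANC == 777))
  # log10-uniform marginal: chi-square on 10,000 draws of Ne_1
  d2 <- sample_priors(pri, 10000, seed = 3)
  lg <- log10(d2$Ne_1)
  br <- seq(2, log10(5e5), length.out = 11)
  obs <- table(cut(lg, br))
  pv <- suppressWarnings(chisq.test(obs)$p.value)
  expect_gt(pv, 0.01)
  # empty feasible region errors
  pri3 <- pri; pri3$min[pri3$param == "t1"] <- 200
  expect_error(sample_priors(pri3, 10, seed = 1))
})

test_that("scenario simulation honors sample sizes, seeds and coalescent theory", {
  spec1 <- scenario_spec(1)
  p <- as.list(prior_midpoint())
  sim <- simulate_scenario(spec1, p, c(Iber = 20, Col = 5, TXL = 5, SNP = 5),
                           n_loci = 50, seed = 5)
  expect_equal(n_samples(sim$panel), 35)
  expect_equal(ncol(sim$panel$hap), 70)    # 2 haplotypes per diploid
  expect_true(sim$panel$phased)
  expect_equal(sort(unique(sim$popmap$population)),
               c("Col", "Iber", "SNP", "TXL"))
  # same seed, same panel
  sim2 <- simulate_scenario(spec1, p, c(Iber = 20, Col = 5, TXL = 5, SNP = 5),
                            n_loci = 50, seed = 5)
  expect_identical(sim$panel$geno, sim2$panel$geno)

  # single constant-size population: mean pairwise coalescence time ~ 2 Ne
  set.seed(6)
  reps <- criollo:::.sim_coalescent_cpp(c(2L), c(400), matrix(0, 0, 5),
                                        200L, 0, FALSE)$tmrca
  se <- sd(reps) / sqrt(length(reps))
  expect_lt(abs(mean(reps) - 800), 3 * se)
})

test_that("a stronger founder bottleneck leaves stronger differentiation", {
  # On always-polymorphic (array-like) loci, absolute diversity is not
  # identified - only the shape of the frequency spectrum - so the clean
  # monotone signature of the founder event is Creole-vs-Iberian FST, which
  # must fall as the bottleneck size Ne_ANC grows (milder founder event).
  # Mean heterozygosity of ascertained loci shows no usable trend; see the
  # methods vignette.
  spec2 <- scenario_spec(2)
  base <- as.list(prior_midpoint())
  base$t1 <- 36; base$t2 <- 89; base$t3 <- 127
  base$Ne_1 <- 57278; base$Ne_2 <- 40765; base$Ne_Iber <- 2500
  fst <- sapply(c(100, 700, 5000), function(na) {
    p <- base; p$Ne_ANC <- na
    set.seed(41)
    mean(replicate(20, {
      cnt <- simulate_scenario_counts(spec2, p,
                                      c(Iber = 5, Col = 10, TXL = 10, SNP = 10),
                                      n_loci = 300)
      s <- criollo:::summarize_counts(cnt$counts, cnt$n_hap)
      mean(s[c("fst_Col_Iber", "fst_TXL_Iber", "fst_SNP_Iber")])
    }))
  })
  expect_true(all(diff(fst) < 0))
})

test_that("migration scenarios simulate and gene flow erodes differentiation", {
  # all eight scenario configs load and build event tables
  p <- as.list(prior_midpoint(prior_table(migration = TRUE)))
  for (sc in 1:8) {
    spec <- scenario_spec(sc)
    ev <- scenario_events(spec, p)
    expect_true(all(diff(ev$events[, "time"]) >= 0))
    expect_true(any(ev$events[, "type"] == 1))   # splits present
    has_mig <- !is.null(spec$migration)
    expect_equal(any(ev$events[, "type"] == 3), has_mig)
  }
  # strong recent Iberia->Creole gene flow (scenario 3) pulls Creole-Iberian
  # FST below the no-migration topology (scenario 1)
  fst_of <- function(sc, m = NULL, seed) {
    pars <- p; if (!is.null(m)) pars$m <- m
    set.seed(seed)
    mean(replicate(10, {
      cnt <- simulate_scenario_counts(scenario_spec(sc), pars,
                                      c(Iber = 10, Col = 10, TXL = 10,
                                        SNP = 10), n_loci = 300)
      s <- criollo:::summarize_counts(cnt$counts, cnt$n_hap)
      mean(s[c("fst_Col_Iber", "fst_TXL_Iber", "fst_SNP_Iber")])
    }))
  }
  expect_lt(fst_of(3, m = 0.05, seed = 45), fst_of(1, seed = 45))
})

test_that("admixture tracks tile the genome and explain every allele", {
  panels <- bn_panels(n_chrom = 3, snps = 100, n_dip = 15, seed = 21)
  alpha <- c(Iberia = 0.76, commercial = 0.12, Africa = 0.03, zebu = 0.09)
  adm <- generate_admixed(panels, alpha, g = 83, recomb_rate = 1e-8,
                          n_samples = 4, seed = 22)
  tr <- adm$truth
  v <- adm$panel$variants
  # tracks tile each chromosome without overlap
  for (sid in unique(tr$sample)) for (h in 1:2) for (cc in unique(tr$chrom)) {
    seg <- tr[tr$sample == sid & tr$haplotype == h & tr$chrom == cc, ]
    seg <- seg[order(seg$start), ]
    expect_equal(seg$start[1], 1)
    if (nrow(seg) > 1)
      expect_true(all(seg$start[-1] == head(seg$end, -1) + 1))
    expect_equal(seg$end[nrow(seg)], max(v$pos[v$chrom == cc]))
  }
  # copy fidelity: every admixed allele appears in some donor haplotype of
  # the recorded ancestry at that site
  labels <- names(panels)
  for (s in 1:2) for (h in 1:2) {
    anc_at <- truth_ancestry_at(tr, labels, v, adm$panel$samples[s], h)
    hapcol <- adm$panel$hap[, 2 * (s - 1) + h]
    for (a in seq_along(labels)) {
      rows <- which(anc_at == a)
      if (!length(rows)) next
      donor_pool <- panels[[labels[a]]]$hap[rows, , drop = FALSE]
      ok <- vapply(seq_along(rows), function(i)
        hapcol[rows[i]] %in% donor_pool[i, ], TRUE)
      expect_true(all(ok))
    }
  }
  # degenerate mixture: single ancestry everywhere
  adm1 <- generate_admixed(panels, c(Iberia = 1, commercial = 0, Africa = 0,
                                     zebu = 0), g = 83, n_samples = 2,
                           seed = 23)
  expect_true(all(adm1$truth$ancestry == "Iberia"))
  # realized genome-wide ancestry near the target across genomes
  adm2 <- generate_admixed(panels, alpha, g = 83, n_samples = 25, seed = 24)
  frac <- with(adm2$truth, tapply(end - start, ancestry, sum))
  frac <- frac / sum(frac)
  expect_lt(max(abs(frac[names(alpha)] - alpha)), 0.04)
  # doubling g roughly doubles the mean track count per chromosome
  n83 <- nrow(adm2$truth)
  adm3 <- generate_admixed(panels, alpha, g = 166, n_samples = 25, seed = 25)
  expect_gt(nrow(adm3$truth) / n83, 1.6)
  expect_lt(nrow(adm3$truth) / n83, 2.4)
})

test_that("plant_sweep copies a shared haplotype and ascertainment subsamples", {
  sim <- simulate_ld_panel(rep(100L, 30), n_chrom = 2, snps_per_chrom = 40,
                           n_sample = 30, seed = 31)
  core <- 20L
  # f = 1 with huge decay: all carriers identical across the chromosome
  sw <- plant_sweep(sim$panel, sim$popmap, "POP", core, f = 1,
                    decay_bp = 1e12, seed = 32)
  chr <- sim$panel$variants$chrom[core]
  rows <- which(sim$panel$variants$chrom == chr)
  haps <- sw$panel$hap[rows, ]
  expect_equal(length(unique(apply(haps, 2, paste, collapse = ""))), 1)
  # f = 0 leaves the panel unchanged
  sw0 <- plant_sweep(sim$panel, sim$popmap, "POP", core, f = 0,
                     decay_bp = 1e5)
  expect_identical(sw0$panel$hap, sim$panel$hap)
  # planted sweep raises EHH near the core vs the unswept panel
  sw8 <- plant_sweep(sim$panel, sim$popmap, "POP", core, f = 0.8,
                     decay_bp = 2e6, seed = 33)
  e1 <- ehh_curve(sw8$panel, core, 1, max_gap = 1e9)
  e0 <- ehh_curve(sim$panel, core, 1, max_gap = 1e9)
  k <- min(nrow(e1), nrow(e0), 8)
  expect_gt(mean(e1$ehh[2:k]), mean(e0$ehh[2:k]))

  # ascertainment: identity case and exact target count
  asc <- ascertain_snps(sim$panel, maf_min = 0, n_target = n_variants(sim$panel))
  expect_equal(asc$variants, sim$panel$variants)
  asc2 <- ascertain_snps(sim$panel, maf_min = 0.1, n_target = 20, seed = 34)
  expect_equal(n_variants(asc2), 20)
  expect_true(all(maf(asc2) >= 0.1))
  expect_warning(ascertain_snps(sim$panel, maf_min = 0.49, n_target = 1000),
                 "fewer")
})
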