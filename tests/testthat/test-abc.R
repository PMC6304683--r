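test_that("summarize returns the 17-statistic vector with sane values", {
  expect_length(summary_stat_names(), 17)
  sim <- simulate_scenario(scenario_spec(1), as.list(prior_midpoint()),
                           c(Iber = 10, Col = 10, TXL = 10, SNP = 10),
                           n_loci = 200, seed = 51)
  s <- summarize(sim$panel, sim$popmap)
  expect_length(s, 17)
  expect_identical(names(s), summary_stat_names())
  expect_true(all(is.finite(s)))
  # two independent samples from one population: pairwise FST ~ 0
  set.seed(52)
  pfreq <- runif(500, 0.1, 0.9)
  counts <- cbind(A = rbinom(500, 200, pfreq), B = rbinom(500, 200, pfreq),
                  C = rbinom(500, 200, pmin(pfreq + 0.2, 1)),
                  D = rbinom(500, 200, pfreq))
  s2 <- criollo:::summarize_counts(counts, c(A = 200, B = 200, C = 200,
                                             D = 200))
  expect_lt(abs(s2["fst_B_A"]), 0.02)
  # hand evaluation of the heterozygosity statistic on a tiny fixture:
  # m = 4 haplotypes, derived count 2 -> H = (m/(m-1)) * 2p(1-p) = 2/3
  cts <- matrix(c(2L, 2L, 2L, 2L), 1, 4,
                dimnames = list(NULL, c("A", "B", "C", "D")))
  s3 <- criollo:::summarize_counts(cts, c(A = 4, B = 4, C = 4, D = 4))
  expect_equal(unname(s3["mean_het_A"]), 2 / 3)
  # monomorphic group: SD of H reported missing
  cts0 <- matrix(c(0L, 2L, 2L, 2L), 1, 4,
                 dimnames = list(NULL, c("A", "B", "C", "D")))
  s4 <- criollo:::summarize_counts(cts0, c(A = 4, B = 4, C = 4, D = 4))
  expect_true(is.na(s4["sd_het_A"]))
})

test_that("prune_correlated drops duplicates but keeps independent columns", {
  set.seed(61)
  m <- matrix(rnorm(400 * 6), 400, 6,
              dimnames = list(NULL, paste0("s", 1:6)))
  m <- cbind(m, s7 = m[, 3])                     # exact duplicate
  kept <- prune_correlated(m, rho_max = 0.95)
  expect_true("s3" %in% kept)
  expect_false("s7" %in% kept)
  # independent random columns are all retained
  expect_length(prune_correlated(m[, 1:6], rho_max = 0.95), 6)
})

test_that("abc_reject matches the exhaustive oracle and the exact count", {
  set.seed(62)
  N <- 200
  st <- matrix(rnorm(N * 5), N, 5, dimnames = list(NULL, paste0("s", 1:5)))
  pars <- data.frame(theta = rnorm(N))
  obs <- setNames(rnorm(5), paste0("s", 1:5))
  rej <- abc_reject(obs, st, pars, retain_fraction = 0.1)
  expect_length(rej$index, 20)
  # brute-force oracle: standardize, Euclidean distance, sort
  z <- scale(st)
  zo <- (obs - attr(z, "scaled:center")) / attr(z, "scaled:scale")
  d <- sqrt(rowSums(sweep(z, 2, zo)^2))
  expect_identical(rej$index, order(d, seq_len(N))[1:20])
  # observed equal to one simulation ranks it first
  obs2 <- st[57, ]
  expect_equal(abc_reject(obs2, st, pars, 0.05)$index[1], 57)
  # degenerate statistic is dropped with a warning
  st2 <- cbind(st, s6 = 1)
  expect_warning(abc_reject(c(obs, s6 = 1), st2, pars, 0.1), "degenerate")
})

test_that("regression adjustment shifts draws correctly", {
  set.seed(63)
  n <- 300
  # linear truth: param = 2 * stat (+ tiny noise); adjusted mean ~ 2 * obs
  st <- matrix(rnorm(n), n, 1, dimnames = list(NULL, "s1"))
  pars <- data.frame(theta = 2 * st[, 1] + rnorm(n, sd = 0.05))
  obs <- c(s1 = 0.7)
  pri <- data.frame(param = "theta", scale = "linear", min = -10, max = 10)
  rej <- abc_reject(obs, st, pars, retain_fraction = 0.5)
  adj <- regression_adjust(rej, obs, pri)
  expect_lt(abs(mean(adj$theta) - 1.4) / 1.4, 0.05)
  # observed at the retained centroid: essentially zero mean shift (the
  # distance weights and leverage correction leave a sub-1e-3 remainder)
  rej_c <- abc_reject(obs, st, pars, 0.5)
  obs_c <- c(s1 = mean(rej_c$stats[, "s1"]))
  adj_c <- regression_adjust(rej_c, obs_c, pri)
  expect_lt(abs(mean(adj_c$theta) - mean(rej_c$params$theta)), 1e-3)
  # parameters independent of the statistics: distribution unchanged (KS)
  pars2 <- data.frame(theta = rnorm(n))
  rej2 <- abc_reject(obs, st, pars2, retain_fraction = 0.5)
  adj2 <- regression_adjust(rej2, obs, pri)
  expect_gt(ks.test(adj2$theta, rej2$params$theta)$p.value, 0.01)
})

test_that("marginal density and posterior P-value behave like a KDE", {
  set.seed(64)
  # 1-D standard normal cloud: MD at 0 ~ phi(0) within KDE error
  st <- matrix(rnorm(2000), ncol = 1, dimnames = list(NULL, "s1"))
  md0 <- marginal_density(st, c(s1 = 0))
  expect_lt(abs(md0 - dnorm(0)) / dnorm(0), 0.1)
  # far outside the cloud: density collapses toward 0
  expect_lt(marginal_density(st, c(s1 = 50)), 1e-8)
  # invariance under joint rescaling of a statistic
  st2 <- cbind(st, s2 = rnorm(2000))
  obs <- c(s1 = 0.3, s2 = -0.2)
  md_a <- marginal_density(st2, obs)
  st3 <- st2; st3[, "s2"] <- st3[, "s2"] * 1000
  obs3 <- obs; obs3["s2"] <- obs3["s2"] * 1000
  expect_equal(marginal_density(st3, obs3), md_a, tolerance = 1e-8)
  # P-value: densest point ~ 1, far point ~ 0
  expect_gt(posterior_pvalue(st, c(s1 = 0)), 0.9)
  expect_lt(posterior_pvalue(st, c(s1 = 50)), 0.01)
  # rank agreement with a brute-force density sort on a uniform cloud
  stu <- matrix(runif(400), ncol = 1, dimnames = list(NULL, "s1"))
  obsu <- c(s1 = 0.5)
  p <- posterior_pvalue(stu, obsu)
  prep <- criollo:::md_prep(stu, obsu)
  dens <- criollo:::kde_logdens(prep$Z, prep$Z)
  dobs <- criollo:::kde_logdens(prep$Z, matrix(prep$zobs, 1))
  expect_equal(p, mean(dens <= dobs))
})

test_that("Bayes factors and scenario comparison follow the MD arithmetic", {
  expect_equal(bayes_factor(10, 5), 2)
  expect_equal(bayes_factor(3, 3), 1)
  expect_warning(bf <- bayes_factor(1, 0), "infinite")
  expect_true(is.infinite(bf))
  md <- c(Sc1 = 10, Sc2 = 100, Sc3 = 40)
  cmp <- compare_scenarios(md)
  expect_equal(cmp$best, "Sc2")
  expect_equal(cmp$ranking, c("Sc2", "Sc3", "Sc1"))
  expect_equal(cmp$rejected, "Sc1")          # 100/40 = 2.5 < 3 keeps Sc3
  expect_equal(diag(cmp$bf), c(Sc1 = 1, Sc2 = 1, Sc3 = 1))
  expect_equal(cmp$bf["Sc1", "Sc3"], 1 / cmp$bf["Sc3", "Sc1"])
  # BF matrix consistency: BF_ij * BF_jk * BF_ki = 1
  expect_equal(cmp$bf["Sc1", "Sc2"] * cmp$bf["Sc2", "Sc3"] *
                 cmp$bf["Sc3", "Sc1"], 1)
  # permuting scenario order permutes the matrix consistently
  cmp2 <- compare_scenarios(md[c(2, 3, 1)])
  expect_equal(cmp2$bf["Sc1", "Sc2"], cmp$bf["Sc1", "Sc2"])
  # single scenario refuses (needs >= 2)
  expect_error(compare_scenarios(md[1]), "at least 2")
})

test_that("posterior summaries recover modes and nested intervals", {
  set.seed(65)
  pri <- data.frame(param = "x", scale = "linear", min = -10, max = 10)
  x <- data.frame(x = rnorm(5000))
  ps <- posterior_summaries(x, pri)
  expect_lt(abs(ps$mode), 0.15)
  expect_equal(ps$q90_lower, -1.645, tolerance = 0.08)
  expect_equal(ps$q90_upper, 1.645, tolerance = 0.08)
  # intervals nested
  expect_lt(ps$q90_lower, ps$q50_lower)
  expect_gt(ps$q90_upper, ps$q50_upper)
  # point mass: mode = value, zero-width intervals
  pm <- posterior_summaries(data.frame(x = rep(3.3, 200)), pri)
  expect_equal(pm$mode, 3.3)
  expect_equal(pm$q50_lower, 3.3)
  expect_equal(pm$q90_upper, 3.3)
  # log10-scale parameter summarized on the log scale and back-transformed
  pri2 <- data.frame(param = "ne", scale = "log10", min = 1, max = 1e6)
  y <- data.frame(ne = 10^rnorm(5000, mean = 3, sd = 0.2))
  ps2 <- posterior_summaries(y, pri2)
  expect_equal(log10(ps2$mode), 3, tolerance = 0.1)
  expect_true(ps2$mode >= ps2$q90_lower && ps2$mode <= ps2$q90_upper)
})
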