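#' ABC configuration
#'
#' @param retain_fraction fraction of simulations kept by rejection (default
#'   0.5%)
#' @param rho_max Spearman threshold for pruning correlated statistics
#' @param bf_reject_threshold Bayes-factor level above which the weaker
#'   scenario is rejected (default 3)
#' @return list of class `abc_config`
#' @export
abc_config <- function(retain_fraction = 0.005, rho_max = 0.95,
                       bf_reject_threshold = 3) {
  stopifnot(retain_fraction > 0, retain_fraction < 1,
            bf_reject_threshold > 1)
  structure(list(retain_fraction = retain_fraction, rho_max = rho_max,
                 bf_reject_threshold = bf_reject_threshold),
            class = "abc_config")
}

#' Names of the default summary-statistic set
#'
#' Seventeen statistics over the four analysis groups (three Creole clusters
#' plus the Iberian pool): per-group mean and SD over loci of unbiased
#' expected heterozygosity, per-group polymorphic-site counts, pairwise FST
#' of each Creole group against the Iberian pool, the pooled FST among the
#' Creole groups, and the global FST. This set is a documented stand-in - the
#' historically used statistic list is not public - and is configurable
#' wherever a summary vector is consumed.
#'
#' @param groups group labels, reference (Iberian) group first
#' @return character vector of 17 names
#' @export
summary_stat_names <- function(groups = c("Iber", "Col", "TXL", "SNP")) {
  ref <- groups[1]; rest <- groups[-1]
  c(paste0("mean_het_", groups), paste0("sd_het_", groups),
    paste0("npoly_", groups), paste0("fst_", rest, "_", ref),
    "fst_creole_mean", "fst_global")
}

# Hudson-style FST from per-group derived counts; ratio of sums over loci.
# counts/sizes: loci x groups. Returns a single value for the group pair set.
hudson_fst <- function(counts, sizes, pairs) {
  num <- den <- 0
  for (pr in pairs) {
    c1 <- counts[, pr[1]]; c2 <- counts[, pr[2]]
    m1 <- sizes[pr[1]]; m2 <- sizes[pr[2]]
    if (m1 < 2 || m2 < 2) next
    p1 <- c1 / m1; p2 <- c2 / m2
    num <- num + sum((p1 - p2)^2 - p1 * (1 - p1) / (m1 - 1) -
                       p2 * (1 - p2) / (m2 - 1))
    den <- den + sum(p1 * (1 - p2) + p2 * (1 - p1))
  }
  if (den <= 0) return(NA_real_)
  num / den
}

# 17 statistics from a derived-count matrix (loci x groups, columns named)
summarize_counts <- function(counts, n_hap,
                             groups = colnames(counts)) {
  counts <- counts[, groups, drop = FALSE]
  m <- n_hap[groups]
  p <- sweep(counts, 2, m, "/")
  het <- sweep(2 * p * (1 - p), 2, m / (m - 1), "*")
  mean_het <- colMeans(het)
  sd_het <- apply(het, 2, function(x) if (any(x > 0)) stats::sd(x) else NA_real_)
  poly <- colSums(counts > 0 & sweep(counts, 2, m, "<"))
  ref <- groups[1]; rest <- groups[-1]
  fst_ref <- vapply(rest, function(g)
    hudson_fst(counts, m, list(c(g, ref))), 0)
  creole_pairs <- utils::combn(rest, 2, simplify = FALSE)
  fst_creole <- hudson_fst(counts, m, creole_pairs)
  all_pairs <- utils::combn(groups, 2, simplify = FALSE)
  fst_global <- hudson_fst(counts, m, all_pairs)
  stats::setNames(c(mean_het, sd_het, poly, fst_ref, fst_creole, fst_global),
                  summary_stat_names(groups))
}

#' Summary-statistic vector for ABC
#'
#' Computes the default 17-statistic summary (see [summary_stat_names()])
#' from a genotype panel, using pooled allele counts per group; identical
#' definitions are applied to simulated allele-count archives so observed
#' and simulated vectors are directly comparable. Deterministic; a group in
#' which every locus is monomorphic yields `NA` for its heterozygosity SD.
#'
#' @param panel a [genotype_panel()]
#' @param popmap a [population_map()]
#' @param groups group labels in fixed order, reference group first
#' @return named numeric vector of length 17
#' @export
summarize <- function(panel, popmap, groups = c("Iber", "Col", "TXL", "SNP")) {
  missing <- setdiff(groups, unique(popmap$population))
  if (length(missing))
    stop("group(s) absent from the population map: ",
         paste(missing, collapse = ", "))
  counts <- sapply(groups, function(g) {
    s <- match(pop_samples(popmap, g), panel$samples)
    rowSums(panel$geno[, s, drop = FALSE], na.rm = TRUE)
  })
  # missing calls are rare on filtered panels; the group's haplotype count
  # is taken as the average number of called alleles per locus
  n_hap <- vapply(groups, function(g) {
    s <- match(pop_samples(popmap, g), panel$samples)
    round(mean(2 * rowSums(!is.na(panel$geno[, s, drop = FALSE]))))
  }, 0)
  summarize_counts(counts, n_hap, groups)
}

#' Prune highly correlated summary statistics
#'
#' Greedy removal in the declared statistic order: visiting columns left to
#' right, a later statistic whose |Spearman rho| with any retained earlier
#' statistic exceeds `rho_max` is dropped.
#'
#' @param sim_stats matrix of simulated summary vectors (rows = simulations)
#' @param rho_max threshold on |Spearman correlation|
#' @return character vector of retained statistic names
#' @export
prune_correlated <- function(sim_stats, rho_max = 0.95) {
  if (nrow(sim_stats) < 2) stop("need at least 2 simulations")
  ok_col <- apply(sim_stats, 2, function(x) stats::sd(x, na.rm = TRUE) > 0)
  rho <- suppressWarnings(
    stats::cor(sim_stats, method = "spearman", use = "pairwise.complete.obs"))
  keep <- logical(ncol(sim_stats))
  for (j in seq_len(ncol(sim_stats))) {
    if (!isTRUE(ok_col[j])) next
    earlier <- which(keep)
    if (!length(earlier) ||
        all(abs(rho[j, earlier]) <= rho_max, na.rm = TRUE))
      keep[j] <- TRUE
  }
  colnames(sim_stats)[keep]
}

#' ABC rejection sampling
#'
#' Euclidean distance between observed and simulated summary vectors after
#' standardizing every statistic by its simulation mean and SD (statistics
#' with zero SD are dropped with a warning). Exactly
#' `ceiling(retain_fraction * N)` closest simulations are kept; distance ties
#' break by simulation index.
#'
#' @param observed named numeric summary vector
#' @param sim_stats matrix of simulated summaries (rows = simulations)
#' @param sim_params data.frame of the generating parameters, same row order
#' @param retain_fraction fraction retained
#' @return list: `index`, `distance` (for the retained rows, closest first),
#'   `params`, `stats`, and the standardization (`center`, `scale`, `used`)
#' @export
abc_reject <- function(observed, sim_stats, sim_params = NULL,
                       retain_fraction = 0.005) {
  N <- nrow(sim_stats)
  if (N < 1 / retain_fraction)
    stop("need at least 1/retain_fraction simulations")
  use <- colnames(sim_stats)
  if (!is.null(names(observed))) use <- intersect(use, names(observed))
  S <- sim_stats[, use, drop = FALSE]
  ctr <- colMeans(S, na.rm = TRUE)
  scl <- apply(S, 2, stats::sd, na.rm = TRUE)
  bad <- !is.finite(scl) | scl == 0
  if (any(bad)) {
    warning("dropping degenerate statistic(s): ",
            paste(use[bad], collapse = ", "))
    use <- use[!bad]; S <- S[, !bad, drop = FALSE]
    ctr <- ctr[!bad]; scl <- scl[!bad]
  }
  Z <- sweep(sweep(S, 2, ctr), 2, scl, "/")
  zobs <- (observed[use] - ctr) / scl
  d2 <- rowSums(sweep(Z, 2, zobs)^2)
  n_keep <- ceiling(retain_fraction * N)
  ord <- order(d2, seq_len(N))[seq_len(n_keep)]
  list(index = ord, distance = sqrt(d2[ord]),
       params = if (!is.null(sim_params)) sim_params[ord, , drop = FALSE],
       stats = sim_stats[ord, use, drop = FALSE],
       center = ctr, scale = scl, used = use)
}

#' Beaumont-style linear regression adjustment
#'
#' For each parameter, a local-linear model of the (sampling-scale)
#' parameter on the standardized retained statistics - weighted by an
#' Epanechnikov kernel on the rejection distance, as in Beaumont-style
#' adjustment - shifts every retained draw to the observed statistics under
#' a homoscedastic linear response: `theta* = theta - (s - s_obs)' beta`.
#' Residuals are leverage-corrected (divided by `sqrt(1 - h_ii)`) before
#' re-centering: with order 10-15 statistics fitted on order 100 retained
#' draws, raw residuals understate the posterior spread and the adjusted
#' intervals undercover; the standardized-residual form restores the
#' marginal variance. Parameters with log10-uniform priors are adjusted on
#' the log10 scale and back-transformed; adjusted draws are clipped to the
#' prior support. A singular design falls back to the unadjusted draws with
#' a warning.
#'
#' @param rej result of [abc_reject()]
#' @param observed the observed summary vector
#' @param prior prior table ([prior_table()]) giving scale and support
#' @return data.frame of adjusted parameter draws
#' @export
regression_adjust <- function(rej, observed, prior = prior_table()) {
  params <- rej$params
  if (is.null(params)) stop("rejection result carries no parameters")
  use <- rej$used
  if (nrow(params) <= length(use) + 1)
    stop("need more retained draws than statistics")
  Z <- sweep(sweep(rej$stats[, use, drop = FALSE], 2, rej$center[use]),
             2, rej$scale[use], "/")
  zobs <- (observed[use] - rej$center[use]) / rej$scale[use]
  D <- sweep(Z, 2, zobs)  # stats relative to observed
  # Epanechnikov weights on the rejection distance (flat if unavailable)
  w <- rep(1, nrow(params))
  if (!is.null(rej$distance) && max(rej$distance) > 0) {
    dmax <- max(rej$distance) * (1 + 1e-9)
    w <- 1 - (rej$distance / dmax)^2
  }
  X <- cbind(1, D)
  # leverage of each retained draw under the weighted design
  hat_ii <- tryCatch({
    Xw <- X * sqrt(w)
    rowSums((Xw %*% solve(crossprod(Xw))) * Xw)
  }, error = function(e) rep(0, nrow(X)))
  infl <- 1 / sqrt(pmax(1 - hat_ii, 0.05))
  out <- params
  for (pn in names(params)) {
    row <- prior[prior$param == pn, ]
    logscale <- nrow(row) == 1 && row$scale == "log10"
    theta <- if (logscale) log10(params[[pn]]) else params[[pn]]
    fit <- tryCatch(stats::lm.wfit(X, theta, w),
                    error = function(e) NULL)
    if (is.null(fit) || anyNA(fit$coefficients)) {
      warning("singular design for parameter ", pn, "; draws left unadjusted")
      next
    }
    pred_obs <- fit$coefficients[1]          # D is centred at the observed
    resid <- theta - as.vector(X %*% fit$coefficients)
    adj <- pred_obs + resid * infl
    if (nrow(row) == 1) {
      lo <- if (logscale) log10(row$min) else row$min
      hi <- if (logscale) log10(row$max) else row$max
      adj <- pmin(pmax(adj, lo), hi)
    }
    out[[pn]] <- if (logscale) 10^adj else adj
  }
  out
}

# log-density of a product-Gaussian KDE fitted on `train` (standardized
# columns assumed), evaluated at rows of `eval`; Silverman bandwidth per
# column. Blocked to bound memory.
kde_logdens <- function(train, eval, bw = NULL) {
  train <- as.matrix(train); eval <- as.matrix(eval)
  n <- nrow(train); k <- ncol(train)
  if (is.null(bw)) {
    bw <- apply(train, 2, stats::sd) * 1.06 * n^(-1 / 5)
    bw[bw <= 0 | !is.finite(bw)] <- 1e-8
  }
  out <- numeric(nrow(eval))
  block <- max(1L, floor(2e6 / n))
  for (s in seq(1, nrow(eval), by = block)) {
    e <- min(s + block - 1, nrow(eval))
    lp <- matrix(0, n, e - s + 1)
    for (j in seq_len(k)) {
      diff <- outer(train[, j], eval[s:e, j], "-") / bw[j]
      lp <- lp + stats::dnorm(diff, log = TRUE) - log(bw[j])
    }
    mx <- apply(lp, 2, max)
    out[s:e] <- mx + log(colMeans(exp(sweep(lp, 2, mx))))
  }
  out
}

#' Marginal density of the observed data under a fitted scenario
#'
#' Product-Gaussian kernel density estimate of the retained simulated summary
#' vectors, with per-statistic Silverman bandwidths, evaluated at the
#' observed vector. Statistics are standardized by the retained mean/SD first
#' so the value is invariant under joint rescaling of a statistic in both
#' simulations and observation.
#'
#' @param retained_stats matrix of retained simulated summaries
#' @param observed observed summary vector (names matched to columns)
#' @return the marginal density (a non-negative scalar)
#' @export
marginal_density <- function(retained_stats, observed) {
  prep <- md_prep(retained_stats, observed)
  exp(kde_logdens(prep$Z, matrix(prep$zobs, 1)))
}

md_prep <- function(retained_stats, observed) {
  use <- colnames(retained_stats)
  if (!is.null(names(observed))) use <- intersect(use, names(observed))
  S <- retained_stats[, use, drop = FALSE]
  ctr <- colMeans(S); scl <- apply(S, 2, stats::sd)
  ok <- is.finite(scl) & scl > 0
  S <- S[, ok, drop = FALSE]
  Z <- sweep(sweep(S, 2, ctr[ok]), 2, scl[ok], "/")
  zobs <- (observed[use][ok] - ctr[ok]) / scl[ok]
  list(Z = Z, zobs = zobs)
}

#' Posterior predictive P-value
#'
#' The fraction of retained simulations whose KDE density is less than or
#' equal to the density of the observed vector - small when the observation
#' sits outside the cloud of retained simulations, close to 1 at its densest
#' point.
#'
#' @inheritParams marginal_density
#' @return P in `[0, 1]`
#' @export
posterior_pvalue <- function(retained_stats, observed) {
  prep <- md_prep(retained_stats, observed)
  ld_obs <- kde_logdens(prep$Z, matrix(prep$zobs, 1))
  ld_all <- kde_logdens(prep$Z, prep$Z)
  mean(ld_all <= ld_obs)
}

#' Bayes factor between two scenarios
#'
#' The quotient of marginal densities, `BF = MD_a / MD_b`.
#' @param md_a,md_b marginal densities
#' @return the Bayes factor (infinite, with a warning, when `md_b` is 0)
#' @export
bayes_factor <- function(md_a, md_b) {
  if (md_b < 0 || md_a < 0) stop("marginal densities must be non-negative")
  if (md_b == 0) {
    warning("zero denominator marginal density; Bayes factor is infinite")
    return(Inf)
  }
  md_a / md_b
}

#' Scenario comparison from marginal densities
#'
#' Builds the full pairwise Bayes-factor matrix, ranks scenarios by marginal
#' density, and rejects every scenario whose BF against the best one exceeds
#' the threshold (conventionally 3).
#'
#' @param md named vector of per-scenario marginal densities
#' @param pvalue optional named vector of posterior P-values
#' @param bf_reject_threshold rejection level
#' @return list of class `model_comparison`: `md`, `pvalue`, `bf` (matrix
#'   with `bf[i, j] = md_i / md_j`), `ranking`, `best`, `rejected`
#' @export
compare_scenarios <- function(md, pvalue = NULL, bf_reject_threshold = 3) {
  if (length(md) < 2) stop("need at least 2 scenarios")
  if (is.null(names(md))) names(md) <- paste0("Sc", seq_along(md))
  bf <- outer(md, md, "/")
  ranking <- names(sort(md, decreasing = TRUE))
  best <- ranking[1]
  rejected <- names(md)[bf[best, ] > bf_reject_threshold]
  structure(list(md = md, pvalue = pvalue, bf = bf, ranking = ranking,
                 best = best, rejected = rejected,
                 threshold = bf_reject_threshold),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("model comparison:", length(x$md), "scenarios; best =", x$best, "\n")
  cat("rejected (BF >", x$threshold, "):",
      if (length(x$rejected)) paste(x$rejected, collapse = ", ") else "none",
      "\n")
  invisible(x)
}

#' Posterior mode and quantile intervals
#'
#' Mode via a kernel density peak on the sampling scale of each parameter's
#' prior (log10 or linear), central 50% and 90% intervals from quantiles,
#' everything back-transformed to the natural scale.
#'
#' @param samples data.frame of (adjusted) posterior draws
#' @param prior prior table giving each parameter's sampling scale
#' @return data.frame: `param`, `mode`, `q50_lower`, `q50_upper`,
#'   `q90_lower`, `q90_upper`
#' @export
posterior_summaries <- function(samples, prior = prior_table()) {
  if (nrow(samples) < 100) stop("need at least 100 posterior draws")
  rows <- lapply(names(samples), function(pn) {
    row <- prior[prior$param == pn, ]
    logscale <- nrow(row) == 1 && row$scale == "log10"
    x <- if (logscale) log10(samples[[pn]]) else samples[[pn]]
    if (stats::sd(x) == 0) {
      mode <- x[1]
    } else {
      dd <- stats::density(x)
      mode <- dd$x[which.max(dd$y)]
    }
    q <- stats::quantile(x, c(0.25, 0.75, 0.05, 0.95), names = FALSE)
    back <- function(v) if (logscale) 10^v else v
    data.frame(param = pn, mode = back(mode),
               q50_lower = back(q[1]), q50_upper = back(q[2]),
               q90_lower = back(q[3]), q90_upper = back(q[4]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
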