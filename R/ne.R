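#' Map physical distance to recombination rate
#'
#' `map_linear` assumes a uniform 1 cM/Mb map (`c = d * 1e-8` Morgans per
#' bp); `map_haldane` additionally applies Haldane's transform to convert map
#' distance to recombination fraction.
#' @param d distance in bp
#' @param cm_per_mb map density
#' @return recombination fraction c
#' @export
map_linear <- function(d, cm_per_mb = 1) d * cm_per_mb * 1e-8

#' @rdname map_linear
#' @export
map_haldane <- function(d, cm_per_mb = 1) {
  0.5 * (1 - exp(-2 * d * cm_per_mb * 1e-8))
}

#' Distance bins targeting a generation range
#'
#' LD at recombination distance `c` reflects effective size roughly
#' `t = 1/(2c)` generations ago, so a target range of generations maps to a
#' range of inter-marker distances (about 1-3.85 Mb for 13-50 generations
#' under a 1 cM/Mb map). Returns distance bin edges whose bins tile the
#' generation range evenly.
#'
#' @param t_min,t_max generation range (defaults 13 and 50)
#' @param n_bins number of bins
#' @param cm_per_mb map density
#' @return numeric vector of distance edges (bp), increasing
#' @export
ne_bins <- function(t_min = 13, t_max = 50, n_bins = 19, cm_per_mb = 1) {
  t_edges <- seq(t_max, t_min, length.out = n_bins + 1)
  1e8 / (2 * t_edges * cm_per_mb)
}

#' Binned adjusted LD by inter-marker distance
#'
#' Every intra-chromosomal marker pair whose distance falls inside the bin
#' edges contributes its composite r-squared; per bin, the mean r-squared is
#' corrected for finite sample size (`- 1/n` for unphased dosage data,
#' `- 1/(2n)` for phased haplotypes) and the bin is mapped to a
#' recombination rate `c` (mean mapped distance of its pairs) and a
#' generation `t = 1/(2c)`. Bins below `min_pairs` are dropped with a
#' warning, as are bins whose corrected r-squared is not positive.
#'
#' @param panel a [genotype_panel()]
#' @param popmap a [population_map()]
#' @param population population label (fewer than 10 individuals warns)
#' @param bin_edges distance bin edges in bp (default [ne_bins()])
#' @param map_fun distance-to-recombination mapping (default [map_linear()])
#' @param min_pairs minimum pair count per bin
#' @param use_haplotypes compute r-squared from haplotypes (phased panels)
#'   instead of dosages
#' @return data.frame of class `ld_bins`: `bin`, `d_lo`, `d_hi`, `c`, `t`,
#'   `r2`, `r2_adj`, `n_pairs`
#' @export
binned_r2 <- function(panel, popmap, population, bin_edges = ne_bins(),
                      map_fun = map_linear, min_pairs = 30L,
                      use_haplotypes = FALSE) {
  ids <- pop_samples(popmap, population)
  if (length(ids) < 10)
    warning("fewer than 10 individuals in ", population)
  n <- length(ids)
  scols <- match(ids, panel$samples)
  nb <- length(bin_edges) - 1
  sum_r2 <- cnt <- sum_c <- numeric(nb)
  for (chr in unique(panel$variants$chrom)) {
    vidx <- which(panel$variants$chrom == chr)
    if (length(vidx) < 2) next
    pos <- panel$variants$pos[vidx]
    if (use_haplotypes && !is.null(panel$hap)) {
      m <- panel$hap[vidx, hap_cols(panel, ids), drop = FALSE]
    } else {
      m <- panel$geno[vidx, scols, drop = FALSE]
    }
    r2 <- r2_block(m)
    dmat <- abs(outer(pos, pos, "-"))
    ut <- upper.tri(dmat)
    d <- dmat[ut]; r <- r2[ut]
    bin <- findInterval(d, bin_edges, rightmost.closed = TRUE)
    ok <- bin >= 1 & bin <= nb & !is.na(r)
    if (!any(ok)) next
    tb <- tapply(r[ok], bin[ok], sum)
    tc <- tapply(map_fun(d[ok]), bin[ok], sum)
    tn <- tapply(rep(1, sum(ok)), bin[ok], sum)
    ii <- as.integer(names(tb))
    sum_r2[ii] <- sum_r2[ii] + tb
    sum_c[ii] <- sum_c[ii] + tc
    cnt[ii] <- cnt[ii] + tn
  }
  corr <- if (use_haplotypes) 1 / (2 * n) else 1 / n
  keep <- cnt >= min_pairs
  if (any(!keep & cnt > 0))
    warning(sum(!keep & cnt > 0), " bin(s) dropped below min_pairs")
  r2m <- sum_r2 / cnt
  cm <- sum_c / cnt
  out <- data.frame(bin = seq_len(nb), d_lo = bin_edges[-(nb + 1)],
                    d_hi = bin_edges[-1], c = cm, t = 1 / (2 * cm),
                    r2 = r2m, r2_adj = r2m - corr, n_pairs = cnt)[keep, ]
  drop_neg <- out$r2_adj <= 0
  if (any(drop_neg))
    warning(sum(drop_neg), " bin(s) dropped with non-positive adjusted r2")
  out <- out[!drop_neg, , drop = FALSE]
  class(out) <- c("ld_bins", "data.frame")
  out
}

#' Effective size from one LD bin
#'
#' Inverts the drift-recombination expectation
#' `E[r2_adj] = 1 / (alpha + 4 Ne c)`:
#' `Ne = (1/(4c)) * (1/r2_adj - alpha)`, dated at `t = 1/(2c)` generations
#' ago. `alpha = 2` applies the mutation-rate modifier (appropriate for real
#' marker data), `alpha = 1` the pure drift form. Non-positive estimates are
#' reported as `NA` (dropped downstream).
#'
#' @param r2_adj sample-size-corrected r-squared
#' @param c recombination rate (Morgans)
#' @param alpha mutation modifier, 1 or 2
#' @return list `t`, `ne`
#' @export
ne_from_bin <- function(r2_adj, c, alpha = 2) {
  stopifnot(c > 0)
  if (is.na(r2_adj) || r2_adj <= 0) return(list(t = 1 / (2 * c), ne = NA_real_))
  ne <- (1 / (4 * c)) * (1 / r2_adj - alpha)
  if (ne <= 0) ne <- NA_real_
  list(t = 1 / (2 * c), ne = ne)
}

#' LD-based effective-size trajectory
#'
#' One `(t, Ne)` point per surviving distance bin (see [binned_r2()] and
#' [ne_from_bin()]), restricted to the target generation window (default
#' 13-50 generations ago) and ordered by increasing `t`. Deterministic given
#' the panel - no randomness is involved.
#'
#' @inheritParams binned_r2
#' @param alpha mutation modifier passed to [ne_from_bin()]
#' @param t_range generations-ago window to keep
#' @return data.frame of class `ne_trajectory`: `t`, `ne` (increasing `t`)
#' @export
ne_trajectory <- function(panel, popmap, population, bin_edges = ne_bins(),
                          map_fun = map_linear, alpha = 2,
                          t_range = c(13, 50), min_pairs = 30L,
                          use_haplotypes = FALSE) {
  bins <- binned_r2(panel, popmap, population, bin_edges, map_fun,
                    min_pairs, use_haplotypes)
  pts <- do.call(rbind, lapply(seq_len(nrow(bins)), function(i) {
    nb <- ne_from_bin(bins$r2_adj[i], bins$c[i], alpha)
    data.frame(t = nb$t, ne = nb$ne)
  }))
  pts <- pts[!is.na(pts$ne) & pts$t >= t_range[1] & pts$t <= t_range[2], ,
             drop = FALSE]
  pts <- pts[order(pts$t), , drop = FALSE]
  rownames(pts) <- NULL
  class(pts) <- c("ne_trajectory", "data.frame")
  pts
}

#' Normalized Ne-slope series (NeS)
#'
#' The slope of each segment linking neighbouring trajectory points
#' (`S_n = (Ne_{n+1} - Ne_n) / (t_{n+1} - t_n)`, with `n` increasing toward
#' the past) is normalized by the median of itself and the two more-past
#' slopes: `NeS_n = (S_n - Xmed_n) / (1 + Xmed_n)` with
#' `Xmed_n = median(S_n, S_{n+1}, S_{n+2})`. A constant-slope trajectory
#' yields NeS identically 0; the two most-past segments have no NeS value
#' (not enough past neighbours); a median of exactly -1 makes the value
#' undefined (`NA`).
#'
#' @param trajectory a data.frame with columns `t` and `ne`, increasing `t`
#'   (as from [ne_trajectory()]), with at least 4 points
#' @return data.frame of class `nes_series`: `n`, `t_mid`, `S`, `X_med`,
#'   `NeS`
#' @export
nes <- function(trajectory) {
  stopifnot(all(c("t", "ne") %in% names(trajectory)))
  if (nrow(trajectory) < 4)
    stop("NeS needs at least 4 trajectory points")
  if (is.unsorted(trajectory$t, strictly = TRUE))
    stop("trajectory must have strictly increasing t")
  tt <- trajectory$t; ne <- trajectory$ne
  K <- length(tt) - 1
  S <- diff(ne) / diff(tt)
  t_mid <- (tt[-1] + tt[-length(tt)]) / 2
  X <- rep(NA_real_, K)
  NeS <- rep(NA_real_, K)
  for (n in seq_len(K - 2)) {
    X[n] <- stats::median(c(S[n], S[n + 1], S[n + 2]))
    NeS[n] <- if (X[n] == -1) NA_real_ else (S[n] - X[n]) / (1 + X[n])
  }
  out <- data.frame(n = seq_len(K), t_mid = t_mid, S = S, X_med = X,
                    NeS = NeS)
  class(out) <- c("nes_series", "data.frame")
  out
}
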