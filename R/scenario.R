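#' Prior table for the colonization-history parameters
#'
#' Eleven parameters describe the founder-bottleneck / expansion / collapse
#' demography: a per-locus mutation rate, seven effective sizes (the two
#' expansion targets `Ne_1`/`Ne_2`, the founding bottleneck `Ne_ANC`, the
#' Iberian source `Ne_Iber` and the three terminal Creole clusters), and the
#' three event times `t1 < t2 < t3` in generations before present. Rates and
#' sizes carry log10-uniform priors, times linear-uniform. Scenarios with
#' gene flow add a backward migration rate `m` (log10-uniform on
#' `[1e-5, 0.1]` per lineage per generation).
#'
#' @param migration include the migration-rate row
#' @return data.frame with columns `param`, `scale` (`"log10"`/`"linear"`),
#'   `min`, `max`
#' @export
prior_table <- function(migration = FALSE) {
  tab <- data.frame(
    param = c("mutation_rate", "Ne_1", "Ne_2", "Ne_ANC", "Ne_Iber",
              "Ne_TXL", "Ne_Col", "Ne_SNP", "t1", "t2", "t3"),
    scale = c(rep("log10", 8), rep("linear", 3)),
    min = c(1e-4, 100, 100, 100, 100, 10, 10, 10, 5, 20, 50),
    max = c(0.05, 5e5, 5e5, 5000, 5e4, 5000, 5e4, 5000, 150, 150, 150),
    stringsAsFactors = FALSE)
  if (migration)
    tab <- rbind(tab, data.frame(param = "m", scale = "log10",
                                 min = 1e-5, max = 0.1))
  tab
}

#' Sample demographic parameters from their priors
#'
#' Log10-scaled parameters are drawn uniformly on the log10 scale and
#' back-transformed; linear parameters uniformly on the natural scale.
#' Draws violating the event-time ordering `t1 < t2 < t3` have their time
#' triple resampled until the ordering holds.
#'
#' @param prior a prior table as from [prior_table()] (user overrides allowed)
#' @param n number of draws
#' @param seed RNG seed (`NULL` to use the current RNG state)
#' @return data.frame of `n` rows, one column per parameter
#' @export
sample_priors <- function(prior = prior_table(), n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (any(prior$min > prior$max)) stop("empty prior range (min > max)")
  draw1 <- function(row, k) {
    if (row$min == row$max) return(rep(row$min, k))
    if (row$scale == "log10")
      10^stats::runif(k, log10(row$min), log10(row$max))
    else stats::runif(k, row$min, row$max)
  }
  out <- as.data.frame(lapply(seq_len(nrow(prior)), function(i)
    draw1(prior[i, ], n)))
  names(out) <- prior$param
  tnames <- intersect(c("t1", "t2", "t3"), names(out))
  if (length(tnames) == 3) {
    trows <- match(tnames, prior$param)
    bad <- which(!(out$t1 < out$t2 & out$t2 < out$t3))
    guard <- 0L
    while (length(bad) > 0) {
      for (k in seq_along(tnames))
        out[bad, tnames[k]] <- draw1(prior[trows[k], ], length(bad))
      bad <- bad[!(out$t1[bad] < out$t2[bad] & out$t2[bad] < out$t3[bad])]
      guard <- guard + 1L
      if (guard > 10000L) stop("cannot satisfy t1 < t2 < t3 under this prior")
    }
  }
  out
}

#' Midpoint of each prior (log-scale geometric midpoint)
#' @param prior a prior table
#' @return named numeric vector
#' @export
prior_midpoint <- function(prior = prior_table()) {
  mid <- ifelse(prior$scale == "log10",
                10^((log10(prior$min) + log10(prior$max)) / 2),
                (prior$min + prior$max) / 2)
  stats::setNames(mid, prior$param)
}

#' Load a demographic scenario specification
#'
#' The eight canonical colonization scenarios ship as editable JSON under
#' `system.file("extdata/scenarios", package = "criollo")`: scenario 1 is the
#' base dispersal topology (the American ancestor founded from Iberia at t3
#' at the bottleneck size, Texas Longhorn splitting at t2, the Colombian and
#' Senepol clusters at t1); scenario 2 adds exponential expansion phases on
#' the American ancestral lineage (reaching `Ne_2` at t2 and `Ne_1` at t1);
#' scenarios 3/4/5 add Iberia-to-Creole migration after t1, before t1, or
#' throughout; scenarios 6/7/8 combine the expansion with each migration
#' pattern.
#'
#' @param scenario an integer 1-8, or a path to a scenario JSON file
#' @return a `scenario_spec` list (populations, splits, sizes, growth,
#'   migration, `generation_length_years`)
#' @export
scenario_spec <- function(scenario) {
  path <- if (is.character(scenario) && file.exists(scenario)) scenario
  else system.file("extdata", "scenarios",
                   sprintf("scenario%d.json", as.integer(scenario)),
                   package = "criollo", mustWork = TRUE)
  spec <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(spec$generation_length_years))
    spec$generation_length_years <- 5
  for (f in c("populations", "splits", "sizes"))
    if (is.null(spec[[f]])) stop("scenario file lacks field: ", f)
  class(spec) <- "scenario_spec"
  spec
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf("scenario_spec #%s: %d populations, %d splits, %s growth phase(s), %s migration epoch(s)\n",
              x$id, length(x$populations), nrow(x$splits),
              if (is.null(x$growth)) 0 else nrow(x$growth),
              if (is.null(x$migration)) 0 else nrow(x$migration)))
  invisible(x)
}

# resolve a symbolic time/size entry ("t1", "Ne_ANC", or a number) against
# the sampled parameters
resolve_sym <- function(x, params) {
  if (is.numeric(x)) return(x)
  suppressWarnings(num <- as.numeric(x))
  if (!is.na(num)) return(num)
  if (!x %in% names(params)) stop("unknown symbol in scenario: ", x)
  as.numeric(params[[x]])
}

#' Build the backward-in-time event table for a scenario
#'
#' Turns the declarative scenario (splits, growth phases, migration epochs)
#' into the time-sorted event rows the coalescent engine consumes.
#' Exponential growth phases are discretized into `growth_steps` log-spaced
#' constant-size epochs; this piecewise-constant approximation is part of the
#' package's stated model.
#'
#' @param spec a [scenario_spec()]
#' @param params named vector/list of parameter values (see [prior_table()])
#' @param growth_steps constant-size steps per growth phase
#' @return list with `events` (matrix: time, type, a, b, x), `pop_sizes`
#'   (present-day sizes by population) and `populations`
#' @export
scenario_events <- function(spec, params, growth_steps = 12L) {
  pops <- spec$populations
  pidx <- function(name) match(name, pops) - 1L
  sizes <- vapply(pops, function(p) {
    s <- spec$sizes[[p]]
    if (is.null(s)) 1000 else resolve_sym(s, params)
  }, 0)
  ev <- list()
  add <- function(time, type, a, b, x) {
    ev[[length(ev) + 1L]] <<- c(time, type, a, b, x)
  }
  if (!is.null(spec$splits) && nrow(spec$splits)) {
    for (i in seq_len(nrow(spec$splits))) {
      s <- spec$splits[i, ]
      add(resolve_sym(s$time, params), 1, pidx(s$derived), pidx(s$ancestral), 0)
    }
  }
  if (!is.null(spec$growth) && NROW(spec$growth)) {
    for (i in seq_len(nrow(spec$growth))) {
      g <- spec$growth[i, ]
      t0 <- resolve_sym(g$start, params); t1 <- resolve_sym(g$end, params)
      n0 <- resolve_sym(g$start_size, params)
      n1 <- resolve_sym(g$end_size, params)
      if (t1 <= t0) stop("growth phase must have end time > start time")
      # backward in time: size is n0 at t0 shrinking (or growing) to n1 at t1
      add(t0, 2, pidx(g$population), 0, n0)
      for (k in seq_len(growth_steps)) {
        tk <- t0 + k * (t1 - t0) / growth_steps
        nk <- n0 * (n1 / n0)^(k / growth_steps)
        add(tk, 2, pidx(g$population), 0, nk)
      }
    }
  }
  if (!is.null(spec$migration) && NROW(spec$migration)) {
    for (i in seq_len(NROW(spec$migration))) {
      mrow <- if (is.data.frame(spec$migration)) spec$migration[i, ]
      else spec$migration[[i]]
      from <- unlist(mrow$from)
      to <- unlist(mrow$to)
      rate <- resolve_sym(mrow$rate[[1]], params)
      t0 <- resolve_sym(mrow$start[[1]], params)
      t1 <- resolve_sym(mrow$end[[1]], params)
      for (f in from) {
        add(t0, 3, pidx(f), pidx(to), rate)
        add(t1, 3, pidx(f), pidx(to), 0)
      }
    }
  }
  events <- do.call(rbind, ev)
  if (is.null(events)) events <- matrix(0, 0, 5)
  events <- events[order(events[, 1], events[, 2]), , drop = FALSE]
  colnames(events) <- c("time", "type", "a", "b", "x")
  list(events = events, pop_sizes = sizes, populations = pops)
}
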