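#' Moran-model parameters for one cell's mtDNA population
#'
#' The mtDNA population of a post-mitotic cell is modelled as a fixed-size
#' Moran process: the cell holds exactly `N` mtDNA molecules; at exponential
#' waiting times `t ~ Exp(N log(2) / t_half)` one molecule, chosen uniformly,
#' is replicated and another, chosen uniformly with replacement (the same
#' molecule can replicate and then die), is destroyed. Each replication
#' introduces `m ~ Binomial(L, nu)` brand-new mutations on the daughter
#' molecule (infinite sites, no back mutation). The population starts free of
#' cryptic mutations.
#'
#' The default per-base mutation probability per replication is
#' `4.6e-8`, consistent with inference from single-cell data at an assumed
#' copy number of 1000; the default half-life of 0.07 years (about 26 days)
#' is in the range reported for mammalian mtDNA turnover.
#'
#' @param N mtDNA copy number per cell (integer, >= 2).
#' @param t_half mtDNA half-life in years (> 0).
#' @param nu mutation probability per base per replication (in `[0, 1e-4]`).
#' @param L mitochondrial genome length in bases (default human, 16569).
#' @return An object of class `moran_params`.
#' @export
moran_params <- function(N = 1000, t_half = 0.07, nu = 4.6e-8, L = 16569L) {
  stopifnot(length(N) == 1, length(t_half) == 1, length(nu) == 1, length(L) == 1)
  if (N < 2) stop("N must be at least 2")
  if (t_half <= 0) stop("t_half must be positive")
  if (nu < 0 || nu > 1e-4) stop("nu must lie in [0, 1e-4]")
  if (L <= 0) stop("L must be positive")
  structure(list(N = as.integer(N), t_half = as.numeric(t_half),
                 nu = as.numeric(nu), L = as.numeric(L)),
            class = "moran_params")
}

#' @export
print.moran_params <- function(x, ...) {
  cat("Moran model parameters:\n")
  cat(sprintf("  N (copy number)      : %d\n", x$N))
  cat(sprintf("  t_half (years)       : %g\n", x$t_half))
  cat(sprintf("  nu (per base per rep): %g\n", x$nu))
  cat(sprintf("  L (genome length)    : %g\n", x$L))
  cat(sprintf("  event rate (1/years) : %g\n", moran_event_rate(x)))
  cat(sprintf("  fixation time (years): %g\n", fixation_time(x)))
  invisible(x)
}

#' Birth-death event rate of the Moran process, in events per year
#' @param params a [moran_params()] object.
#' @export
moran_event_rate <- function(params) {
  params$N * log(2) / params$t_half
}

#' Expected time to fixation of the mtDNA population
#'
#' The expected time for the whole population of `N` molecules to descend
#' from a single common ancestor. Under the Kingman coalescent this equals
#' `2 * (1 - 1/N)` pairwise-coalescence times; the mean pairwise coalescence
#' time of the Moran process is `N * t_half / (2 * log(2))` years (events
#' occur at rate `N log(2) / t_half` and any given ordered pair of lineages
#' merges with probability `2 / N^2` per event). The constant can be
#' checked empirically with [pair_coalescence_oracle()].
#'
#' This timescale is the unit of the dimensionless mitochondrial age `W`:
#' `W = age_years / fixation_time(params)`.
#'
#' @param params a [moran_params()] object.
#' @return Expected fixation time in years.
#' @export
fixation_time <- function(params) {
  2 * (1 - 1 / params$N) * params$N * params$t_half / (2 * log(2))
}

#' Convert chronological age to mitochondrial age W and back
#'
#' `W` is a proportion of the expected time to fixation ([fixation_time()]).
#' In event units, scaled age `W` corresponds to `W * N * (N - 1)`
#' birth-death events.
#'
#' @param age_years chronological age(s) in years.
#' @param w mitochondrial age(s), dimensionless.
#' @param params a [moran_params()] object.
#' @return Numeric vector.
#' @export
w_from_age <- function(age_years, params) age_years / fixation_time(params)

#' @rdname w_from_age
#' @export
age_from_w <- function(w, params) w * fixation_time(params)

# internal: run the marginal-representation ensemble and return, per
# observation time, a data.frame(cell, freq, fixed) plus events per cell
moran_ensemble_raw <- function(params, n_cells, obs_times, duration,
                               poisson_events = TRUE) {
  stopifnot(n_cells >= 1, duration >= 0)
  obs_times <- as.numeric(obs_times)
  if (any(obs_times < 0) || any(obs_times > duration + 1e-12))
    stop("obs_times must lie within [0, duration]")
  if (is.unsorted(obs_times)) stop("obs_times must be sorted increasing")
  lambda <- moran_event_rate(params) * duration
  obs_frac <- if (duration > 0) obs_times / duration else rep(0, length(obs_times))
  raw <- cpp_moran_cells(params$N, as.integer(n_cells), lambda, obs_frac,
                         params$L, params$nu, poisson_events)
  states <- lapply(raw, function(s) {
    data.frame(cell = s$cell, freq = s$count / params$N,
               fixed = s$count == params$N)
  })
  list(states = states, events_per_cell = attr(raw, "events_per_cell"))
}

#' Simulate the mtDNA population of one cell forward in time
#'
#' Event-driven, exact simulation of the infinite-sites neutral Moran model.
#' Mutations are tracked by their copy count; under neutrality each
#' mutation's marginal copy-count process is exactly the Moran birth-death
#' chain, so the site frequency spectrum is simulated without storing
#' per-molecule genomes (see [simulate_cell_genomes()] for the per-molecule
#' reference implementation used in small-N cross-checks).
#'
#' @param params a [moran_params()] object.
#' @param duration_years length of the simulation (the cell's age).
#' @param obs_times observation times in years, sorted, within
#'   `[0, duration_years]`. Defaults to the final time only.
#' @param seed optional integer seed.
#' @return An object of class `mutation_trajectory`: a list with `times`,
#'   `states` (per time, a data.frame with the segregating mutation
#'   frequencies and a fixed flag), `fixed_counts` (per time), `n_events`,
#'   and `params`.
#' @export
simulate_cell <- function(params, duration_years, obs_times = duration_years,
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (duration_years < 0) stop("duration_years must be non-negative")
  res <- moran_ensemble_raw(params, 1L, obs_times, duration_years)
  structure(list(
    times = as.numeric(obs_times),
    states = lapply(res$states, function(s) s[, c("freq", "fixed")]),
    fixed_counts = vapply(res$states, function(s) sum(s$fixed), integer(1)),
    n_events = as.numeric(res$events_per_cell[1]),
    params = params
  ), class = "mutation_trajectory")
}

#' @export
print.mutation_trajectory <- function(x, ...) {
  cat(sprintf("Moran mutation trajectory: %d observation time(s), %g events\n",
              length(x$times), x$n_events))
  for (i in seq_along(x$times)) {
    s <- x$states[[i]]
    cat(sprintf("  t = %-8g  segregating: %-5d fixed: %d\n",
                x$times[i], sum(!s$fixed), x$fixed_counts[i]))
  }
  invisible(x)
}

#' Per-molecule Moran simulation (small-N reference implementation)
#'
#' Simulates the same process as [simulate_cell()] but stores every
#' molecule's full mutation set, so linkage between mutations on one genome
#' is represented exactly. Intended for small `N` and short horizons as an
#' independent oracle for the marginal-representation engine.
#'
#' @inheritParams simulate_cell
#' @return As [simulate_cell()].
#' @export
simulate_cell_genomes <- function(params, duration_years,
                                  obs_times = duration_years, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  N <- params$N
  rate <- moran_event_rate(params)
  obs_times <- as.numeric(obs_times)
  if (any(obs_times < 0) || any(obs_times > duration_years + 1e-12))
    stop("obs_times must lie within [0, duration_years]")
  genomes <- rep(list(integer(0)), N)  # mutation ids carried by each molecule
  next_id <- 1L
  t_now <- 0
  obs_idx <- 1L
  states <- vector("list", length(obs_times))
  snapshot <- function() {
    ids <- unlist(genomes, use.names = FALSE)
    if (length(ids) == 0)
      return(data.frame(freq = numeric(0), fixed = logical(0),
                        id = integer(0)))
    tab <- table(ids)
    data.frame(freq = as.numeric(tab) / N, fixed = as.numeric(tab) == N,
               id = as.integer(names(tab)))
  }
  repeat {
    t_next <- t_now + rexp(1, rate)
    while (obs_idx <= length(obs_times) && obs_times[obs_idx] < t_next) {
      states[[obs_idx]] <- snapshot()
      obs_idx <- obs_idx + 1L
    }
    if (obs_idx > length(obs_times) || t_next > duration_years) break
    t_now <- t_next
    parent <- sample.int(N, 1)
    dier <- sample.int(N, 1)   # with replacement: may equal parent
    m <- rbinom(1, params$L, params$nu)
    daughter <- genomes[[parent]]
    if (m > 0) {
      daughter <- c(daughter, seq.int(next_id, next_id + m - 1L))
      next_id <- next_id + m
    }
    genomes[[dier]] <- daughter
  }
  while (obs_idx <= length(obs_times)) {
    states[[obs_idx]] <- snapshot()
    obs_idx <- obs_idx + 1L
  }
  structure(list(
    times = obs_times,
    states = lapply(states, function(s) s[, c("freq", "fixed")]),
    fixed_counts = vapply(states, function(s) sum(s$fixed), integer(1)),
    n_events = NA_real_,
    params = params
  ), class = "mutation_trajectory")
}

#' Pooled cryptic site frequency spectrum of a simulated cell ensemble
#'
#' Simulates `n_cells` independent cells to `age_years` and pools every
#' mutation frequency above `floor` (fixed mutations enter at frequency 1)
#' into a cryptic SFS. This ensemble is the ground-truth, forward-simulation
#' counterpart of the coalescent expectation computed by [expected_csfs()].
#'
#' @param params a [moran_params()] object.
#' @param n_cells number of independent cells.
#' @param age_years age of every cell.
#' @param floor detection floor: only frequencies strictly above it enter.
#' @param bins number of equal-width heteroplasmy bins on
#'   `(floor, homoplasmy_cut)`.
#' @param homoplasmy_cut frequencies at or above this value are pooled into
#'   the terminal homoplasmic bin.
#' @param dequantize map a segregating copy count `i` to a heteroplasmy
#'   drawn uniformly from `((i - 1/2)/N, (i + 1/2)/N)` instead of the grid
#'   value `i/N` (default `TRUE`). The reference-N simulation discretizes
#'   heteroplasmy to multiples of `1/N` while the estimand is the continuum
#'   spectrum of a cell with thousands of mtDNA copies; dequantization
#'   removes the grid artifact and makes spectra comparable across
#'   reference N. Fixed mutations stay at heteroplasmy 1. Set `FALSE` for
#'   exact discrete-state work.
#' @param seed optional integer seed.
#' @return A `cryptic_sfs` object (see [build_csfs()]); the per-cell
#'   mutation counts above the floor are attached as attribute
#'   `"per_cell_counts"`.
#' @export
ensemble_csfs <- function(params, n_cells, age_years, floor = 0.10,
                          bins = 20, homoplasmy_cut = 0.95,
                          dequantize = TRUE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  res <- moran_ensemble_raw(params, n_cells, age_years, age_years)
  st <- res$states[[1]]
  if (dequantize && nrow(st) > 0) {
    cnt <- round(st$freq * params$N)
    jit <- (cnt + runif(nrow(st), -0.5, 0.5)) / params$N
    st$freq <- ifelse(st$fixed, 1, jit)
  }
  keep <- st$freq > floor
  h <- st$freq[keep]
  cells <- st$cell[keep]
  sfs <- new_csfs(h, donor = "moran_ensemble", floor = floor, bins = bins,
                  homoplasmy_cut = homoplasmy_cut, n_cells = n_cells)
  counts <- tabulate(cells, nbins = n_cells)
  attr(sfs, "per_cell_counts") <- counts
  sfs
}

#' Threshold-crossing and fixed-mutation summaries across ages
#'
#' Simulates an ensemble observed at each requested age (the same cells are
#' followed through time, so per-cell curves are internally consistent) and
#' reports, per age and heteroplasmy threshold, the fraction of cells
#' carrying at least one mutation at frequency `>= threshold`, plus the mean
#' number of fixed (homoplasmic) mutations per cell, with Monte-Carlo
#' standard errors.
#'
#' @param params a [moran_params()] object.
#' @param ages sorted vector of ages in years.
#' @param thresholds heteroplasmy thresholds (a mutation qualifies at
#'   frequency `>= threshold`; threshold 1 therefore means fixed).
#' @param n_cells ensemble size.
#' @param seed optional integer seed.
#' @return A list with `fractions` (data.frame: age, threshold, fraction,
#'   se) and `fixed` (data.frame: age, mean_fixed, se).
#' @export
summarize_ages <- function(params, ages, thresholds = c(0.6, 0.95, 1.0),
                           n_cells = 500, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.unsorted(ages)) stop("ages must be sorted increasing")
  res <- moran_ensemble_raw(params, n_cells, ages, max(ages))
  frac <- do.call(rbind, lapply(seq_along(ages), function(i) {
    st <- res$states[[i]]
    do.call(rbind, lapply(thresholds, function(th) {
      hit <- unique(st$cell[st$freq >= th])
      p <- length(hit) / n_cells
      data.frame(age = ages[i], threshold = th, fraction = p,
                 se = sqrt(p * (1 - p) / n_cells))
    }))
  }))
  fixed <- do.call(rbind, lapply(seq_along(ages), function(i) {
    st <- res$states[[i]]
    per_cell <- tabulate(st$cell[st$fixed], nbins = n_cells)
    data.frame(age = ages[i], mean_fixed = mean(per_cell),
               se = sd(per_cell) / sqrt(n_cells))
  }))
  list(fractions = frac, fixed = fixed)
}

#' Mean pairwise coalescence time of two mtDNA lineages
#'
#' Backward-in-time pairwise merge process equivalent to lineage tracking in
#' the forward Moran model: birth-death events occur at rate
#' `N log(2) / t_half` and any given pair of lineages merges with
#' probability `2 / N^2` per event (either lineage may be the daughter of
#' the other). The mean coalescence time is therefore proportional to
#' `N * t_half`; this function estimates it by direct simulation and is used
#' to calibrate the constant linking mitochondrial age `W` to years.
#'
#' @param params a [moran_params()] object.
#' @param n_reps number of simulated pairs (>= 1000).
#' @param seed optional integer seed.
#' @return List with `mean` (years), `se`, and `analytic`
#'   (`N * t_half / (2 log 2)`).
#' @export
pair_coalescence_oracle <- function(params, n_reps = 1e4, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n_reps < 1e3) stop("n_reps must be at least 1000")
  N <- params$N
  rate <- moran_event_rate(params)
  n_events <- rgeom(n_reps, 2 / N^2) + 1
  times <- rgamma(n_reps, shape = n_events, rate = rate)
  list(mean = mean(times), se = sd(times) / sqrt(n_reps),
       analytic = N * params$t_half / (2 * log(2)))
}

#' Empirical fixation probability of a single new neutral mutation
#'
#' Introduces one mutation at copy count 1 and follows its Moran birth-death
#' walk to absorption (loss or fixation). Under neutrality the fixation
#' probability is `1/N`.
#'
#' @param params a [moran_params()] object (only `N` is used).
#' @param n_trials number of independent mutations tracked.
#' @param seed optional integer seed.
#' @return List with `estimate`, `se`, `n_fixed`, `n_trials`, `expected`.
#' @export
fixation_probability <- function(params, n_trials = 2e4, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_fixed <- cpp_fixation_trials(params$N, as.integer(n_trials))
  p <- n_fixed / n_trials
  list(estimate = p, se = sqrt(p * (1 - p) / n_trials),
       n_fixed = n_fixed, n_trials = n_trials, expected = 1 / params$N)
}
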