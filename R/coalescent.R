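# Coalescent / forward-Kolmogorov model of the out-of-equilibrium cryptic
# SFS and Bayesian inference of mitochondrial age W and scaled mutation
# rate Theta = N * nu.
#
# Scaled time: W = 1 is the expected time for the cell's mtDNA population
# to fix (descend from a single ancestor), i.e. N * (N - 1) birth-death
# events. In scaled time the normalized spectrum is independent of the
# bookkeeping copy number, so expectations are computed once at a modest
# reference N and reused for any donor.

# Expected-spectrum table: deterministic propagation of the marginal
# birth-death chain (the forward Kolmogorov equations of the Moran
# frequency process) with unit mutation influx. e[i] is the expected
# number of segregating mutations at copy number i per unit per-event
# per-genome mutation rate; `fixed` accumulates mass absorbed at N.
# Expected counts per cell for a donor with per-base rate Theta scale as
# L * Theta / N * e (N-independent in the large-N sense; the residual
# discretization is what the backend-equivalence tests bound).
csfs_model_table <- function(N_ref = 50, floor = 0.10, homoplasmy_cut = 0.95,
                             bins = 20, w_max = 3) {
  key <- paste("tbl", N_ref, floor, homoplasmy_cut, bins, w_max, sep = "|")
  hit <- .mitocrypt_cache[[key]]
  if (!is.null(hit)) return(hit)
  N <- N_ref
  n_w <- round(w_max / 0.025) + 1
  i <- seq_len(N - 1)
  p <- i / N
  flux <- p * (1 - p)           # per-event up (= down) probability from i
  W_grid <- seq(0, w_max, length.out = n_w)
  K_grid <- round(W_grid * N * (N - 1))
  e <- numeric(N - 1)
  fixed <- 0
  E_mat <- matrix(0, n_w, N - 1)
  F_vec <- numeric(n_w)
  ptr <- 1L
  K_max <- max(K_grid)
  for (k in 0:K_max) {
    while (ptr <= n_w && K_grid[ptr] == k) {
      E_mat[ptr, ] <- e
      F_vec[ptr] <- fixed
      ptr <- ptr + 1L
    }
    if (k == K_max) break
    mv <- e * flux
    e_new <- e - 2 * mv
    e_new[2:(N - 1)] <- e_new[2:(N - 1)] + mv[1:(N - 2)]
    e_new[1:(N - 2)] <- e_new[1:(N - 2)] + mv[2:(N - 1)]
    fixed <- fixed + mv[N - 1]
    e_new[1] <- e_new[1] + 1   # unit influx: one new mutation per event
    e <- e_new
  }
  freqs <- i / N
  # Continuum binning: the reference-N chain discretizes heteroplasmy to
  # multiples of 1/N, while the estimand is the continuum spectrum (real
  # cells carry thousands of copies).  Each state's mass is therefore
  # spread uniformly over ((i - 1/2)/N, (i + 1/2)/N) before binning, the
  # deterministic counterpart of the dequantization in ensemble_csfs().
  lo <- (i - 0.5) / N
  hi <- (i + 0.5) / N
  edges <- c(seq(floor, homoplasmy_cut, length.out = bins + 1), 1)
  mass <- matrix(0, n_w, bins + 1L)
  for (b in seq_len(bins + 1L)) {
    ov <- pmax(0, pmin(hi, edges[b + 1]) - pmax(lo, edges[b])) / (hi - lo)
    mass[, b] <- E_mat %*% ov
  }
  mass[, bins + 1L] <- mass[, bins + 1L] + F_vec
  # per-cell expected counts per unit L * Theta
  mass_theta <- mass / N
  total_theta <- rowSums(mass_theta)
  hom_theta <- mass_theta[, bins + 1L]
  out <- list(N_ref = N, floor = floor, homoplasmy_cut = homoplasmy_cut,
              bins = bins, W_grid = W_grid,
              breaks = c(seq(floor, homoplasmy_cut, length.out = bins + 1), 1),
              mass_theta = mass_theta, total_theta = total_theta,
              hom_theta = hom_theta, freqs = freqs,
              E_theta = E_mat / N, F_theta = F_vec / N)
  .mitocrypt_cache[[key]] <- out
  out
}

# expected per-cell count per unit L*Theta above a frequency threshold
# (inclusive), interpolated over W; same interval-spreading convention as
# the binned table
model_count_above <- function(tbl, W, threshold) {
  N <- tbl$N_ref
  i <- seq_len(N - 1)
  lo <- (i - 0.5) / N
  hi <- (i + 0.5) / N
  ov <- pmax(0, pmin(hi, 1) - pmax(lo, threshold)) / (hi - lo)
  curve <- as.numeric(tbl$E_theta %*% ov) + tbl$F_theta
  approx(tbl$W_grid, curve, xout = W, rule = 2)$y
}

#' Expected cryptic site frequency spectrum at scaled age W
#'
#' Computes the expected normalized heteroplasmy histogram (including the
#' homoplasmic bin) and the expected number of observed cryptic mutations
#' per cell, for a cell population that started mutation-free and has
#' evolved for a scaled age `W` (units of the expected fixation time) with
#' scaled per-base mutation rate `theta = N * nu`.
#'
#' Two backends are available: `"matrix"` (default) propagates the forward
#' Kolmogorov equations of the marginal Moran frequency chain exactly at a
#' reference copy number; `"simulation"` runs a seed-fixed forward Moran
#' ensemble ([ensemble_csfs()]) at the same reference copy number with time
#' rescaling. The coalescent guarantees the normalized spectrum in scaled
#' time does not depend on the copy number, so a modest reference N serves
#' for any donor; the two backends must agree and the simulation ensemble
#' is the ground-truth oracle.
#'
#' @param W scaled mitochondrial age (>= 0).
#' @param theta scaled per-base mutation rate `N * nu` (> 0).
#' @param L genome length in bases (default human mtDNA).
#' @param floor detection floor; the spectrum conditions on `h > floor`.
#' @param homoplasmy_cut terminal-bin threshold (default 0.95).
#' @param bins number of equal-width bins on `(floor, homoplasmy_cut)`.
#' @param N_ref reference copy number for the computation (default 50).
#' @param backend `"matrix"` or `"simulation"`.
#' @param n_cells_sim,seed simulation-backend ensemble size and seed.
#' @return List with `breaks`, `probs` (normalized expected histogram),
#'   `expected_count` (mutations above the floor per cell),
#'   `expected_homoplasmic` (homoplasmic-bin expected count per cell),
#'   `W`, `theta`, and `empty` (`TRUE` when `W = 0`, where the model is a
#'   point mass on "no mutations").
#' @export
expected_csfs <- function(W, theta, L = 16569, floor = 0.10,
                          homoplasmy_cut = 0.95, bins = 20, N_ref = 50,
                          backend = c("matrix", "simulation"),
                          n_cells_sim = 4000, seed = 1) {
  backend <- match.arg(backend)
  stopifnot(W >= 0, theta > 0)
  tbl <- csfs_model_table(N_ref, floor, homoplasmy_cut, bins,
                          w_max = max(3, ceiling(W)))
  if (W == 0) {
    return(list(breaks = tbl$breaks, probs = rep(NA_real_, bins + 1),
                expected_count = 0, expected_homoplasmic = 0,
                W = W, theta = theta, empty = TRUE, backend = backend))
  }
  if (backend == "matrix") {
    mass <- apply(tbl$mass_theta, 2, function(col)
      approx(tbl$W_grid, col, xout = W, rule = 2)$y)
    mass <- mass * L * theta
  } else {
    params <- moran_params(N = N_ref, t_half = 1, nu = theta / N_ref, L = L)
    age <- age_from_w(W, params)
    sfs <- ensemble_csfs(params, n_cells_sim, age, floor = floor,
                         bins = bins, homoplasmy_cut = homoplasmy_cut,
                         seed = seed)
    mass <- sfs$counts / n_cells_sim
  }
  total <- sum(mass)
  list(breaks = tbl$breaks,
       probs = if (total > 0) mass / total else rep(NA_real_, bins + 1),
       expected_count = total,
       expected_homoplasmic = mass[bins + 1],
       W = W, theta = theta, empty = total == 0, backend = backend)
}

#' Log-likelihood of observed cryptic heteroplasmies under the model
#'
#' The likelihood combines a multinomial term for the binned spectrum shape
#' (which depends on `W` only) with a Poisson term for the total number of
#' observed mutations, whose mean `n_cells * L * theta * c(W)` scales
#' linearly in `theta`. Observations at or below the floor are a
#' validation error: the model conditions on `h > floor` exactly as the
#' calling pipeline does.
#'
#' @param h observed cryptic heteroplasmies (all strictly above `floor`).
#' @param n_cells number of retained cells the observations came from.
#' @param W,theta model parameters.
#' @param homoplasmic `"joint"` bins homoplasmic mutations inside the same
#'   multinomial; `"separate"` gives them their own Poisson accumulation
#'   term and restricts the multinomial to segregating bins.
#' @inheritParams expected_csfs
#' @return Log-likelihood (finite for all valid parameters with `W > 0`).
#' @export
csfs_loglik <- function(h, n_cells, W, theta, L = 16569, floor = 0.10,
                        homoplasmy_cut = 0.95, bins = 20, N_ref = 50,
                        homoplasmic = c("joint", "separate")) {
  homoplasmic <- match.arg(homoplasmic)
  if (any(h <= floor))
    stop("observations at or below the detection floor: filter upstream")
  tbl <- csfs_model_table(N_ref, floor, homoplasmy_cut, bins,
                          w_max = max(3, ceiling(W)))
  mass <- apply(tbl$mass_theta, 2, function(col)
    approx(tbl$W_grid, col, xout = W, rule = 2)$y)
  obs <- new_csfs(if (length(h)) h else numeric(0), donor = "obs",
                  floor = floor, bins = bins,
                  homoplasmy_cut = homoplasmy_cut)
  x <- obs$counts
  loglik_from_mass(x, mass, n_cells, L * theta, homoplasmic, bins)
}

# shared kernel: x = observed bin counts, mass = per-cell expected bin
# counts per unit L*Theta, scale = L * theta
loglik_from_mass <- function(x, mass, n_cells, scale, homoplasmic, bins) {
  lam_bins <- n_cells * scale * mass
  if (homoplasmic == "joint") {
    lam_tot <- sum(lam_bins)
    m <- sum(x)
    p <- if (lam_tot > 0) lam_bins / lam_tot else rep(0, length(lam_bins))
    ll <- dpois(m, lam_tot, log = TRUE)
    term <- ifelse(x > 0, x * log(p), 0)
    ll + sum(ifelse(x > 0 & p == 0, -Inf, term))
  } else {
    seg <- seq_len(bins)
    hom <- bins + 1L
    lam_seg <- sum(lam_bins[seg])
    m_seg <- sum(x[seg])
    p <- if (lam_seg > 0) lam_bins[seg] / lam_seg else rep(0, bins)
    term <- ifelse(x[seg] > 0, x[seg] * log(p), 0)
    dpois(m_seg, lam_seg, log = TRUE) +
      sum(ifelse(x[seg] > 0 & p == 0, -Inf, term)) +
      dpois(x[hom], lam_bins[hom], log = TRUE)
  }
}

#' Simulate a synthetic donor's cryptic heteroplasmies at known (W, theta)
#'
#' Forward-Moran ensemble at a reference copy number with time rescaling:
#' the ground-truth generator for parameter-recovery experiments.
#'
#' @inheritParams expected_csfs
#' @param n_cells number of cells in the donor.
#' @return Numeric vector of heteroplasmies above the floor (attribute
#'   `"n_cells"` records the ensemble size).
#' @export
simulate_donor <- function(W, theta, n_cells, L = 16569, floor = 0.10,
                           N_ref = 50, seed = NULL) {
  params <- moran_params(N = N_ref, t_half = 1, nu = theta / N_ref, L = L)
  age <- age_from_w(W, params)
  sfs <- ensemble_csfs(params, n_cells, age, floor = floor, seed = seed)
  h <- sfs$h
  attr(h, "n_cells") <- n_cells
  h
}

#' Bayesian fit of mitochondrial age W and scaled mutation rate Theta
#'
#' Fits the out-of-equilibrium coalescent cSFS model to one donor's
#' observed cryptic heteroplasmies by posterior evaluation on a dense
#' (W, log10 Theta) grid: uniform prior on `W`, log-uniform prior on
#' `Theta` (both configurable). Returns the maximum a posteriori point,
#' central 95 percent credible intervals from the marginal posteriors, and
#' seeded posterior samples. With zero observed mutations and weak data
#' the posterior reproduces the prior. Ties in the posterior maximum are
#' broken toward smaller `W`.
#'
#' @param h observed cryptic heteroplasmies, all strictly above `floor`
#'   (may be empty).
#' @param n_cells number of retained cells for the donor.
#' @param floor detection floor used in calling (default 0.10).
#' @param prior_w range of the uniform prior on W (default `c(0, 3)`).
#' @param prior_log10_theta range of the log-uniform prior on Theta
#'   (default `c(-7, -2)`).
#' @param n_theta number of Theta grid points (default 121; the W grid is
#'   the model table's native grid restricted to the prior).
#' @param n_samples posterior samples to draw (default 4000).
#' @param seed integer seed for the posterior samples.
#' @inheritParams csfs_loglik
#' @return An object of class `mito_fit`.
#' @export
mito_fit <- function(h, n_cells, floor = 0.10, homoplasmy_cut = 0.95,
                     bins = 20, N_ref = 50, L = 16569,
                     prior_w = c(0, 3), prior_log10_theta = c(-7, -2),
                     n_theta = 121, n_samples = 4000,
                     homoplasmic = c("joint", "separate"), seed = 1) {
  homoplasmic <- match.arg(homoplasmic)
  h <- as.numeric(h)
  if (any(h <= floor))
    stop("observations at or below the detection floor: filter upstream")
  stopifnot(n_cells >= 1, diff(prior_w) > 0, diff(prior_log10_theta) > 0)
  tbl <- csfs_model_table(N_ref, floor, homoplasmy_cut, bins,
                          w_max = max(3, ceiling(prior_w[2])))
  w_sel <- tbl$W_grid >= prior_w[1] & tbl$W_grid <= prior_w[2]
  W_grid <- tbl$W_grid[w_sel]
  mass_grid <- tbl$mass_theta[w_sel, , drop = FALSE]
  theta_grid <- 10^seq(prior_log10_theta[1], prior_log10_theta[2],
                       length.out = n_theta)
  obs <- new_csfs(h, donor = "fit", floor = floor, bins = bins,
                  homoplasmy_cut = homoplasmy_cut)
  x <- obs$counts
  ll <- matrix(NA_real_, length(W_grid), n_theta)
  for (i in seq_along(W_grid)) {
    for (j in seq_len(n_theta)) {
      ll[i, j] <- loglik_from_mass(x, mass_grid[i, ], n_cells,
                                   L * theta_grid[j], homoplasmic, bins)
    }
  }
  ll_max <- max(ll[is.finite(ll)])
  post <- exp(ll - ll_max)
  post[!is.finite(post)] <- 0
  evidence <- log(sum(post)) + ll_max - log(length(post))
  post <- post / sum(post)
  # MAP: first maximum in column-major order = smallest W at ties
  map_idx <- arrayInd(which.max(post), dim(post))
  map <- c(W = W_grid[map_idx[1]], theta = theta_grid[map_idx[2]])
  marg_w <- rowSums(post)
  marg_t <- colSums(post)
  ci <- rbind(W = grid_quantiles(W_grid, marg_w, c(0.025, 0.975)),
              theta = grid_quantiles(theta_grid, marg_t, c(0.025, 0.975)))
  colnames(ci) <- c("2.5%", "97.5%")
  set.seed(seed)
  cells <- sample.int(length(post), n_samples, replace = TRUE, prob = post)
  ij <- arrayInd(cells, dim(post))
  dw <- if (length(W_grid) > 1) diff(W_grid[1:2]) else 0
  dlt <- if (n_theta > 1) diff(log10(theta_grid[1:2])) else 0
  samples <- data.frame(
    W = W_grid[ij[, 1]] + runif(n_samples, -dw / 2, dw / 2),
    theta = 10^(log10(theta_grid[ij[, 2]]) + runif(n_samples, -dlt / 2, dlt / 2)))
  samples$W <- pmax(prior_w[1], pmin(prior_w[2], samples$W))
  structure(list(
    map = map, ci = ci, samples = samples, posterior = post,
    W_grid = W_grid, theta_grid = theta_grid, log_evidence = evidence,
    h = h, n_cells = n_cells, observed_counts = x, breaks = obs$breaks,
    settings = list(floor = floor, homoplasmy_cut = homoplasmy_cut,
                    bins = bins, N_ref = N_ref, L = L,
                    prior_w = prior_w,
                    prior_log10_theta = prior_log10_theta,
                    homoplasmic = homoplasmic, seed = seed,
                    grid_dim = dim(post))
  ), class = "mito_fit")
}

# central quantiles of a discrete grid posterior, with linear interpolation
grid_quantiles <- function(grid, weights, probs) {
  w <- weights / sum(weights)
  cdf <- cumsum(w)
  vapply(probs, function(p) {
    k <- which(cdf >= p)[1]
    if (is.na(k)) return(grid[length(grid)])
    if (k == 1) return(grid[1])
    # linear interpolation between grid points by cdf
    c0 <- cdf[k - 1]
    grid[k - 1] + (grid[k] - grid[k - 1]) * (p - c0) / (cdf[k] - c0)
  }, numeric(1))
}

#' Convert a scaled mutation rate Theta to a per-base rate nu
#'
#' `Theta = N * nu`, so under an assumed copy number `N` the per-base
#' per-replication mutation rate is `nu = Theta / N`.
#'
#' @param theta scaled mutation rate(s).
#' @param N assumed mtDNA copy number per cell.
#' @return `nu`, same length as `theta`.
#' @export
rate_from_theta <- function(theta, N) {
  if (any(N <= 0)) stop("N must be positive")
  theta / N
}

#' @rdname rate_from_theta
#' @param nu per-base per-replication mutation rate(s).
#' @export
theta_from_rate <- function(nu, N) {
  if (any(N <= 0)) stop("N must be positive")
  nu * N
}

#' @export
print.mito_fit <- function(x, ...) {
  cat("Coalescent cSFS fit (grid posterior)\n")
  cat(sprintf("  observations : %d cryptic heteroplasmies from %d cells\n",
              length(x$h), x$n_cells))
  cat(sprintf("  MAP  W      = %.3f   (95%% CI %.3f - %.3f)\n",
              x$map["W"], x$ci["W", 1], x$ci["W", 2]))
  cat(sprintf("  MAP  Theta  = %.3g   (95%% CI %.3g - %.3g)\n",
              x$map["theta"], x$ci["theta", 1], x$ci["theta", 2]))
  invisible(x)
}

#' @export
coef.mito_fit <- function(object, ...) object$map

#' @export
summary.mito_fit <- function(object, N = 1000, ...) {
  nu <- rate_from_theta(object$map[["theta"]], N)
  nu_ci <- rate_from_theta(object$ci["theta", ], N)
  out <- list(map = object$map, ci = object$ci, nu = nu, nu_ci = nu_ci,
              N_assumed = N, n_obs = length(object$h),
              n_cells = object$n_cells,
              log_evidence = object$log_evidence,
              settings = object$settings)
  class(out) <- "summary.mito_fit"
  out
}

#' @export
print.summary.mito_fit <- function(x, ...) {
  cat("Coalescent cSFS fit summary\n")
  cat(sprintf("  %d cryptic mutations from %d cells\n", x$n_obs, x$n_cells))
  cat(sprintf("  mitochondrial age W : MAP %.3f, 95%% CI [%.3f, %.3f]\n",
              x$map["W"], x$ci["W", 1], x$ci["W", 2]))
  cat(sprintf("  scaled rate Theta   : MAP %.3g, 95%% CI [%.3g, %.3g]\n",
              x$map["theta"], x$ci["theta", 1], x$ci["theta", 2]))
  cat(sprintf("  per-base rate nu    : %.3g (assuming N = %d mtDNA per cell)\n",
              x$nu, x$N_assumed))
  cat(sprintf("  log evidence proxy  : %.2f\n", x$log_evidence))
  invisible(x)
}

#' @export
residuals.mito_fit <- function(object, ...) {
  s <- object$settings
  exp_sfs <- expected_csfs(object$map[["W"]], object$map[["theta"]],
                           L = s$L, floor = s$floor,
                           homoplasmy_cut = s$homoplasmy_cut,
                           bins = s$bins, N_ref = s$N_ref)
  obs_p <- if (sum(object$observed_counts) > 0)
    object$observed_counts / sum(object$observed_counts)
  else rep(0, length(object$observed_counts))
  obs_p - exp_sfs$probs
}

#' @export
simulate.mito_fit <- function(object, nsim = 1, seed = NULL,
                              use_map = TRUE, ...) {
  if (!is.null(seed)) set.seed(seed)
  s <- object$settings
  out <- vector("list", nsim)
  for (k in seq_len(nsim)) {
    pars <- if (use_map) object$map else {
      i <- sample.int(nrow(object$samples), 1)
      c(W = object$samples$W[i], theta = object$samples$theta[i])
    }
    ex <- expected_csfs(pars[["W"]], pars[["theta"]], L = s$L,
                        floor = s$floor,
                        homoplasmy_cut = s$homoplasmy_cut,
                        bins = s$bins, N_ref = s$N_ref)
    m <- rpois(1, object$n_cells * ex$expected_count)
    if (m == 0 || ex$empty) { out[[k]] <- numeric(0); next }
    b <- sample.int(length(ex$probs), m, replace = TRUE, prob = ex$probs)
    lo <- ex$breaks[b]
    hi <- ex$breaks[b + 1]
    out[[k]] <- runif(m, lo, hi)
  }
  out
}

#' Lifetime prediction curves from a fitted model
#'
#' Converts chronological ages to scaled ages using the assumed copy
#' number and mtDNA half-life, then computes (a) the expected number of
#' homoplasmic mutations per cell versus age together with its first and
#' second derivatives (the speed and acceleration of mitochondrial
#' ageing), and (b) the fraction of cells expected to carry at least one
#' mutation at heteroplasmy at or above each threshold (mutation counts
#' are Poisson, so the fraction is `1 - exp(-lambda)`).
#'
#' @param object a [mito_fit()] object (or a list with elements `W` -- not
#'   used -- and `theta`; only `theta` and the fit settings are read).
#' @param ages chronological ages in years.
#' @param thresholds heteroplasmy thresholds for the crossing curves.
#' @param N assumed mtDNA copy number per cell (unit conversion).
#' @param t_half assumed mtDNA half-life in years.
#' @param df equivalent degrees of freedom of the smoothing spline fitted
#'   to the homoplasmy curve before differentiating (the expectation is
#'   tabulated on a discrete scaled-time grid, so raw finite differences
#'   of the interpolant carry grid-scale noise).
#' @param ... unused.
#' @return List with `homoplasmic` (data.frame: age, W, mean_homoplasmic,
#'   speed, acceleration) and `fractions` (data.frame: age, threshold,
#'   fraction).
#' @export
predict.mito_fit <- function(object, ages = 0:100,
                             thresholds = c(0.6, 0.95, 1.0),
                             N = 1000, t_half = 0.07,
                             df = 10, ...) {
  s <- object$settings
  theta <- object$map[["theta"]]
  params <- moran_params(N = N, t_half = t_half,
                         nu = min(rate_from_theta(theta, N), 1e-4))
  W <- w_from_age(ages, params)
  tbl <- csfs_model_table(s$N_ref, s$floor, s$homoplasmy_cut, s$bins,
                          w_max = max(3, ceiling(max(W))))
  # spline interpolation: the homoplasmy curve is differentiated twice, so
  # piecewise-linear interpolation over the W grid would leave spikes
  hom_count <- s$L * theta *
    pmax(0, stats::spline(tbl$W_grid, tbl$hom_theta, xout = W,
                          method = "natural")$y)
  if (length(ages) >= 8 && df >= 2) {
    ss <- stats::smooth.spline(ages, hom_count,
                               df = min(df, length(ages) - 2))
    speed <- stats::predict(ss, ages, deriv = 1)$y
    accel <- stats::predict(ss, ages, deriv = 2)$y
  } else {
    speed <- finite_diff(ages, hom_count)
    accel <- finite_diff(ages, speed)
  }
  homoplasmic <- data.frame(age = ages, W = W, mean_homoplasmic = hom_count,
                            speed = speed, acceleration = accel)
  fractions <- do.call(rbind, lapply(thresholds, function(th) {
    lam <- s$L * theta * model_count_above(tbl, W, th)
    data.frame(age = ages, threshold = th, fraction = 1 - exp(-lam))
  }))
  list(homoplasmic = homoplasmic, fractions = fractions)
}

finite_diff <- function(x, y) {
  n <- length(x)
  if (n < 3) return(rep(NA_real_, n))
  d <- numeric(n)
  d[2:(n - 1)] <- (y[3:n] - y[1:(n - 2)]) / (x[3:n] - x[1:(n - 2)])
  d[1] <- (y[2] - y[1]) / (x[2] - x[1])
  d[n] <- (y[n] - y[n - 1]) / (x[n] - x[n - 1])
  d
}

#' @export
plot.mito_fit <- function(x, ...) {
  s <- x$settings
  old <- par(mfrow = c(1, 2))
  on.exit(par(old))
  ex <- expected_csfs(x$map[["W"]], x$map[["theta"]], L = s$L,
                      floor = s$floor, homoplasmy_cut = s$homoplasmy_cut,
                      bins = s$bins, N_ref = s$N_ref)
  obs_p <- if (sum(x$observed_counts) > 0)
    x$observed_counts / sum(x$observed_counts) else x$observed_counts * 0
  mids <- (x$breaks[-length(x$breaks)] + x$breaks[-1]) / 2
  bp <- barplot(obs_p, main = "cSFS: observed vs fitted",
                ylab = "proportion", xlab = "heteroplasmy bin")
  points(bp, ex$probs, pch = 19, col = "red")
  legend("topright", legend = c("observed", "fitted"),
         fill = c("grey", NA), border = c("black", NA),
         pch = c(NA, 19), col = c(NA, "red"), bty = "n")
  image(x$W_grid, log10(x$theta_grid), x$posterior,
        xlab = "W", ylab = "log10 Theta", main = "posterior")
  points(x$map[["W"]], log10(x$map[["theta"]]), pch = 3, col = "white")
  invisible(x)
}
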