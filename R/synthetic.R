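# Synthetic multi-donor cohorts with known ground truth: Moran-evolved
# cryptic mutations, planted shared/common variants, negative-binomial
# depth and per-base sequencing error.

#' Configuration for a synthetic single-cell cohort
#'
#' Defaults emulate a full-length scRNA-seq pancreas-style cohort: eight
#' donors spanning one month to 54 years, some hundreds of cells per donor,
#' deep mtDNA coverage, and a small per-base error rate.
#'
#' @param n_donors number of donors.
#' @param ages_years donor ages (non-negative), length `n_donors`.
#' @param cells_per_donor cells sampled per donor.
#' @param moran a [moran_params()] object governing the within-cell mtDNA
#'   dynamics; the Moran duration of each cell equals its donor's age.
#' @param shared_variant_rate expected number of planted non-cryptic
#'   (shared, e.g. developmental) variants per donor.
#' @param common_variant_sites mtDNA sites planted across more than three
#'   donors (classified `common` downstream).
#' @param depth_model list with `mean_depth` (reads) and `dispersion`
#'   (negative-binomial size).
#' @param error_rate per-base miscall probability, in `[0, 0.01]`.
#' @param species species label written to metadata.
#' @param seed master seed; all sub-streams derive from it.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_donors = 8,
                          ages_years = c(1 / 12, 5, 22, 38, 44, 48, 51, 54),
                          cells_per_donor = 300,
                          moran = moran_params(),
                          shared_variant_rate = 3,
                          common_variant_sites = c(73, 2706, 7028, 14766),
                          depth_model = list(mean_depth = 2000,
                                             dispersion = 4),
                          error_rate = 5e-4,
                          species = "human",
                          seed = 1L) {
  if (length(ages_years) != n_donors)
    stop("ages_years must have length n_donors")
  if (any(ages_years < 0)) stop("ages must be non-negative")
  if (error_rate < 0 || error_rate > 0.01)
    stop("error_rate must lie in [0, 0.01]")
  if (depth_model$mean_depth <= 0) stop("mean_depth must be positive")
  stopifnot(inherits(moran, "moran_params"), cells_per_donor >= 1)
  structure(list(n_donors = as.integer(n_donors),
                 ages_years = as.numeric(ages_years),
                 cells_per_donor = as.integer(cells_per_donor),
                 moran = moran,
                 shared_variant_rate = shared_variant_rate,
                 common_variant_sites = as.integer(common_variant_sites),
                 depth_model = depth_model,
                 error_rate = error_rate,
                 species = species,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Generate a synthetic cohort with known ground truth
#'
#' Each cell's cryptic mutations are an independent Moran-model realization
#' of length equal to the donor's age, so true cryptic heteroplasmies carry
#' coalescent structure. Cryptic sites are drawn without replacement within
#' a donor (so each cryptic mutation is unique to one cell) and never
#' collide with planted shared or common sites. Shared variants are drawn
#' once per donor at a donor-level frequency and binomially down-sampled
#' into each cell; common variants are planted the same way across more
#' than three donors when the cohort is large enough.
#'
#' @param config a [cohort_config()] object.
#' @return An object of class `true_cohort`: list with `cells` (data.frame:
#'   cell, donor, age_years, species), `mutations` (data.frame: cell,
#'   donor, pos, ref, alt, freq, origin), `reference` (character vector of
#'   reference bases over the genome), `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  mp <- config$moran
  L <- as.integer(mp$L)
  bases <- c("A", "C", "G", "T")
  reference <- sample(bases, L, replace = TRUE)
  donors <- sprintf("D%02d", seq_len(config$n_donors))
  blocked <- config$common_variant_sites
  if (any(blocked < 1 | blocked > L))
    stop("common_variant_sites outside the genome")

  cells <- data.frame(
    cell = sprintf("%s_c%04d", rep(donors, each = config$cells_per_donor),
                   rep(seq_len(config$cells_per_donor), config$n_donors)),
    donor = rep(donors, each = config$cells_per_donor),
    age_years = rep(config$ages_years, each = config$cells_per_donor),
    species = config$species, row.names = NULL)

  alt_of <- function(pos) {
    vapply(pos, function(p) sample(setdiff(bases, reference[p]), 1), "")
  }

  mut_list <- list()
  # common variants: planted in > 3 donors (all donors when n_donors <= 4)
  n_plant <- if (config$n_donors > 4) max(4L, ceiling(config$n_donors * 0.8))
             else config$n_donors
  common_alt <- alt_of(config$common_variant_sites)
  for (i in seq_along(config$common_variant_sites)) {
    pos <- config$common_variant_sites[i]
    in_donors <- sample(donors, n_plant)
    for (d in in_donors) {
      f <- runif(1, 0.2, 0.8)
      dc <- cells$cell[cells$donor == d]
      k <- rbinom(length(dc), mp$N, f)
      sel <- k > 0
      if (!any(sel)) next
      mut_list[[length(mut_list) + 1L]] <- data.frame(
        cell = dc[sel], donor = d, pos = pos, ref = reference[pos],
        alt = common_alt[i], freq = k[sel] / mp$N, origin = "common")
    }
  }

  for (di in seq_along(donors)) {
    d <- donors[di]
    age <- config$ages_years[di]
    dc <- cells$cell[cells$donor == d]
    taken <- blocked
    # shared (developmental-like) variants for this donor
    n_shared <- rpois(1, config$shared_variant_rate)
    if (n_shared > 0) {
      pos_s <- sample(setdiff(seq_len(L), taken), n_shared)
      taken <- c(taken, pos_s)
      for (pos in pos_s) {
        f <- runif(1, 0.1, 0.8)
        k <- rbinom(length(dc), mp$N, f)
        sel <- k > 0
        if (!any(sel)) next
        mut_list[[length(mut_list) + 1L]] <- data.frame(
          cell = dc[sel], donor = d, pos = pos, ref = reference[pos],
          alt = alt_of(pos), freq = k[sel] / mp$N, origin = "shared")
      }
    }
    # cryptic mutations: independent Moran realizations per cell
    raw <- moran_ensemble_raw(mp, length(dc), age, age)
    st <- raw$states[[1]]
    if (nrow(st) > 0) {
      avail <- setdiff(seq_len(L), taken)
      if (nrow(st) > length(avail))
        stop("genome too short for the number of cryptic mutations")
      pos_c <- sample(avail, nrow(st))
      mut_list[[length(mut_list) + 1L]] <- data.frame(
        cell = dc[st$cell], donor = d, pos = pos_c,
        ref = reference[pos_c], alt = alt_of(pos_c),
        freq = st$freq, origin = "cryptic")
    }
  }

  mutations <- if (length(mut_list)) do.call(rbind, mut_list)
               else data.frame(cell = character(0), donor = character(0),
                               pos = integer(0), ref = character(0),
                               alt = character(0), freq = numeric(0),
                               origin = character(0))
  rownames(mutations) <- NULL
  structure(list(cells = cells, mutations = mutations,
                 reference = reference, config = config),
            class = "true_cohort")
}

#' @export
print.true_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d donors, %d cells, %d true mutations\n",
              x$config$n_donors, nrow(x$cells), nrow(x$mutations)))
  if (nrow(x$mutations))
    print(table(x$mutations$origin))
  invisible(x)
}

#' Render a true cohort into noisy base counts
#'
#' Draws per-(cell, site) depth from a negative binomial whose mean is
#' modulated by a log-normal site-specific multiplier (mimicking
#' transcript-coverage unevenness), samples alternate reads binomially at
#' the true frequency, then applies per-read miscalls uniformly over the
#' other three bases. Sites without mutations emit reference reads plus
#' error.
#'
#' Only the mutated sites plus `n_background` mutation-free background
#' sites (the same set for every cell, so site-level QC is meaningful) are
#' rendered; the remaining genome is implicitly unobserved.
#'
#' @param truth a [generate_cohort()] result.
#' @param depth_model,error_rate override the cohort config (optional).
#' @param seed optional integer seed.
#' @param n_background number of mutation-free sites to render.
#' @return A base-count data.frame (`cell`, `donor`, `pos`, `A`, `C`, `G`,
#'   `T`) with the reference attached as attribute `"reference"`.
#' @export
render_base_counts <- function(truth, depth_model = NULL, error_rate = NULL,
                               seed = NULL, n_background = 400) {
  stopifnot(inherits(truth, "true_cohort"))
  if (is.null(depth_model)) depth_model <- truth$config$depth_model
  if (is.null(error_rate)) error_rate <- truth$config$error_rate
  if (error_rate < 0 || error_rate > 0.01)
    stop("error_rate must lie in [0, 0.01]")
  if (!is.null(seed)) set.seed(seed)
  L <- length(truth$reference)
  bases <- c("A", "C", "G", "T")
  mut_sites <- sort(unique(truth$mutations$pos))
  bg_pool <- setdiff(seq_len(L), mut_sites)
  bg <- sort(sample(bg_pool, min(n_background, length(bg_pool))))
  sites <- sort(c(mut_sites, bg))
  n_cells <- nrow(truth$cells)
  n_sites <- length(sites)

  # site-specific coverage multipliers, shared across cells
  mult <- exp(rnorm(n_sites, 0, 0.5))
  mult <- mult / mean(mult)

  cell <- rep(truth$cells$cell, each = n_sites)
  donor <- rep(truth$cells$donor, each = n_sites)
  pos <- rep(sites, times = n_cells)
  depth <- rnbinom(n_cells * n_sites,
                   size = depth_model$dispersion,
                   mu = depth_model$mean_depth * rep(mult, times = n_cells))

  ref <- truth$reference[pos]
  true_counts <- matrix(0, nrow = length(pos), ncol = 4,
                        dimnames = list(NULL, bases))
  idx_mut <- match(paste(cell, pos),
                   paste(truth$mutations$cell, truth$mutations$pos))
  has_mut <- !is.na(idx_mut)
  alt_reads <- integer(length(pos))
  if (any(has_mut)) {
    f <- truth$mutations$freq[idx_mut[has_mut]]
    alt_reads[has_mut] <- rbinom(sum(has_mut), depth[has_mut], f)
    alt_base <- truth$mutations$alt[idx_mut[has_mut]]
    for (b in bases) {
      sel <- which(has_mut)[alt_base == b]
      true_counts[sel, b] <- alt_reads[sel]
    }
  }
  ref_reads <- depth - alt_reads
  for (b in bases) {
    sel <- ref == b
    true_counts[sel, b] <- true_counts[sel, b] + ref_reads[sel]
  }

  # per-read miscalls: from the true counts, each read is miscalled with
  # probability error_rate, landing uniformly on the other three bases
  final <- true_counts
  if (error_rate > 0) {
    for (b in bases) {
      src <- true_counts[, b]
      err <- rbinom(length(src), src, error_rate)
      final[, b] <- final[, b] - err
      others <- setdiff(bases, b)
      e1 <- rbinom(length(err), err, 1 / 3)
      e2 <- rbinom(length(err), err - e1, 1 / 2)
      e3 <- err - e1 - e2
      final[, others[1]] <- final[, others[1]] + e1
      final[, others[2]] <- final[, others[2]] + e2
      final[, others[3]] <- final[, others[3]] + e3
    }
  }

  out <- data.frame(cell = cell, donor = donor, pos = pos,
                    A = final[, "A"], C = final[, "C"],
                    G = final[, "G"], T = final[, "T"], row.names = NULL)
  attr(out, "reference") <- truth$reference
  out
}

#' Assign pathology classes to a substitution universe
#'
#' Deterministically (given the seed) assigns each substitution one of
#' `synonymous`, `low`, `high`, `noncoding` with the given proportions,
#' emulating a pathogenicity-scored annotation table.
#'
#' @param sites data.frame with columns `pos`, `ref`, `alt`; duplicate
#'   (pos, alt) entries are rejected.
#' @param proportions probabilities for (synonymous, low, high, noncoding).
#' @param seed optional integer seed.
#' @return data.frame `pos`, `ref`, `alt`, `class`.
#' @export
make_annotation_table <- function(sites,
                                  proportions = c(synonymous = 0.25,
                                                  low = 0.35, high = 0.15,
                                                  noncoding = 0.25),
                                  seed = NULL) {
  if (anyDuplicated(paste(sites$pos, sites$alt)))
    stop("duplicate (pos, alt) entries in sites")
  stopifnot(length(proportions) == 4, all(proportions >= 0),
            abs(sum(proportions) - 1) < 1e-8)
  if (!is.null(seed)) set.seed(seed)
  classes <- c("synonymous", "low", "high", "noncoding")
  data.frame(pos = sites$pos, ref = sites$ref, alt = sites$alt,
             class = sample(classes, nrow(sites), replace = TRUE,
                            prob = proportions),
             row.names = NULL)
}

#' All possible substitutions of a reference sequence
#'
#' The substitution universe used to build synthetic annotation tables and
#' opportunity counts.
#'
#' @param reference character vector of reference bases.
#' @param positions positions to include (default all).
#' @return data.frame `pos`, `ref`, `alt`.
#' @export
substitution_universe <- function(reference, positions = seq_along(reference)) {
  bases <- c("A", "C", "G", "T")
  ref <- reference[positions]
  out <- do.call(rbind, lapply(bases, function(b) {
    sel <- ref != b
    data.frame(pos = positions[sel], ref = ref[sel], alt = b)
  }))
  out <- out[order(out$pos, out$alt), , drop = FALSE]
  rownames(out) <- NULL
  out
}
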