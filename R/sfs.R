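# Cryptic site frequency spectra and the summary statistics computed on them.

# internal constructor shared by build_csfs() and ensemble_csfs().
# Equal-width bins on (floor, homoplasmy_cut) plus one terminal bin
# [homoplasmy_cut, 1] holding homoplasmic-like mutations.
new_csfs <- function(h, donor, floor, bins, homoplasmy_cut, n_cells = NA) {
  stopifnot(bins >= 1, floor >= 0, homoplasmy_cut > floor, homoplasmy_cut <= 1)
  h <- as.numeric(h)
  if (any(h <= floor) || any(h > 1))
    stop("all heteroplasmies must lie in (floor, 1]")
  width <- (homoplasmy_cut - floor) / bins
  breaks <- c(seq(floor, homoplasmy_cut, length.out = bins + 1), 1)
  idx <- if (length(h)) {
    as.integer(ifelse(h >= homoplasmy_cut, bins + 1L,
                      pmin(bins, pmax(1L, ceiling((h - floor) / width)))))
  } else integer(0)
  counts <- tabulate(idx, nbins = bins + 1L)
  m <- length(h)
  structure(list(
    donor = donor,
    h = h,
    breaks = breaks,
    counts = counts,
    density = if (m > 0) counts / m else rep(0, bins + 1L),
    n_mutations = m,
    n_cells = n_cells,
    floor = floor,
    homoplasmy_cut = homoplasmy_cut,
    empty = m == 0L
  ), class = "cryptic_sfs")
}

#' Build a donor's cryptic site frequency spectrum
#'
#' Collects the heteroplasmies of all retained cryptic mutations of one
#' donor and bins them into a normalized histogram: equal-width bins on
#' `(floor, homoplasmy_cut)` plus a terminal homoplasmic bin aggregating
#' `h >= homoplasmy_cut`.
#'
#' @param vt a classified [VariantTable][call_variants()] (data.frame).
#' @param donor donor id to extract.
#' @param bins number of equal-width heteroplasmy bins.
#' @param homoplasmy_cut heteroplasmy at or above which a mutation is
#'   counted as homoplasmic-like (default 0.95).
#' @param floor the report floor below which no heteroplasmy is present;
#'   defaults to the `report_floor` attribute left by [classify_variants()].
#' @return An object of class `cryptic_sfs`. If the donor has no cryptic
#'   mutations the object is returned with `empty = TRUE`.
#' @export
build_csfs <- function(vt, donor, bins = 20, homoplasmy_cut = 0.95,
                       floor = NULL) {
  if (is.null(floor)) floor <- attr(vt, "report_floor")
  if (is.null(floor)) floor <- 0.10
  if (!donor %in% vt$donor) stop("donor not present in variant table: ", donor)
  rows <- vt[vt$donor == donor & vt$classification == "cryptic", , drop = FALSE]
  n_cells <- length(unique(vt$cell[vt$donor == donor]))
  new_csfs(rows$h, donor = donor, floor = floor, bins = bins,
           homoplasmy_cut = homoplasmy_cut, n_cells = n_cells)
}

#' @export
print.cryptic_sfs <- function(x, ...) {
  cat(sprintf("Cryptic SFS for donor '%s'\n", x$donor))
  if (x$empty) {
    cat("  (empty: no cryptic mutations)\n")
    return(invisible(x))
  }
  cat(sprintf("  %d mutations over %s cells; floor %g, homoplasmic cut %g\n",
              x$n_mutations, format(x$n_cells), x$floor, x$homoplasmy_cut))
  cat(sprintf("  homoplasmic-bin mass: %.3f\n",
              x$density[length(x$density)]))
  invisible(x)
}

#' @export
plot.cryptic_sfs <- function(x, main = NULL, ...) {
  if (is.null(main)) main <- sprintf("cSFS, donor %s", x$donor)
  nb <- length(x$counts)
  labs <- sprintf("%.2f", x$breaks[-length(x$breaks)])
  labs[nb] <- sprintf(">=%.2f", x$homoplasmy_cut)
  barplot(x$density, names.arg = labs, las = 2, main = main,
          xlab = "heteroplasmy", ylab = "proportion of cryptic mutations",
          ...)
  invisible(x)
}

#' @export
as.data.frame.cryptic_sfs <- function(x, ...) {
  nb <- length(x$counts)
  data.frame(bin_left = x$breaks[seq_len(nb)],
             bin_right = x$breaks[seq_len(nb) + 1],
             count = x$counts, density = x$density)
}

#' Per-cell mitochondrial mutation load
#'
#' The load of a cell with cryptic heteroplasmies `h_1 ... h_m` at threshold
#' `t` is `sum(h_j * (h_j > t))`: only heteroplasmies strictly greater than
#' the threshold contribute (a value exactly equal to `t` contributes
#' nothing). By default only non-synonymous cryptic mutations count.
#'
#' @param vt a classified (and, if `exclude_synonymous`, annotated)
#'   [VariantTable][call_variants()]; may contain one cell or many.
#' @param t load threshold (default 0.10).
#' @param exclude_synonymous drop mutations annotated `synonymous` before
#'   summing (default `TRUE`).
#' @return A data.frame with one row per cell present in `vt`: `cell`,
#'   `donor`, `load`, `n_contributing`, `threshold`.
#' @export
mutation_load <- function(vt, t = 0.10, exclude_synonymous = TRUE) {
  cells <- unique(vt[, c("cell", "donor")])
  rows <- vt[vt$classification == "cryptic", , drop = FALSE]
  if (exclude_synonymous && "pathology" %in% names(rows))
    rows <- rows[rows$pathology != "synonymous", , drop = FALSE]
  rows <- rows[rows$h > t, , drop = FALSE]
  load <- setNames(rep(0, nrow(cells)), cells$cell)
  nc <- setNames(rep(0L, nrow(cells)), cells$cell)
  if (nrow(rows) > 0) {
    agg <- tapply(rows$h, rows$cell, sum)
    load[names(agg)] <- agg
    cnt <- table(rows$cell)
    nc[names(cnt)] <- as.integer(cnt)
  }
  data.frame(cell = cells$cell, donor = cells$donor,
             load = unname(load[cells$cell]),
             n_contributing = unname(nc[cells$cell]),
             threshold = t, row.names = NULL)
}

#' Rank-biserial correlation difference between two heteroplasmy sets
#'
#' Over all `|G1| * |G2|` pairs, let `f` be the fraction of pairs where the
#' `G1` member is strictly greater and `u` the fraction where the `G2`
#' member is strictly greater (ties count to neither). The rank-biserial
#' correlation difference is the difference `f - u`, ranging from -1 (every `G2` value
#' exceeds every `G1` value) to 1 (every `G1` value exceeds every `G2`
#' value); 0 means either direction is equally likely.
#'
#' @param g1,g2 non-empty numeric vectors (heteroplasmies, or any values
#'   to be compared by rank).
#' @return A single number in `[-1, 1]`.
#' @export
rbc_difference <- function(g1, g2) {
  if (inherits(g1, "cryptic_sfs")) g1 <- g1$h
  if (inherits(g2, "cryptic_sfs")) g2 <- g2$h
  if (length(g1) == 0 || length(g2) == 0)
    stop("rbc_difference requires two non-empty sets")
  s2 <- sort(g2)
  n1 <- length(g1); n2 <- length(g2)
  n_less <- findInterval(g1, s2, left.open = TRUE)  # g2 values < each g1
  n_leq <- findInterval(g1, s2)                      # g2 values <= each g1
  f <- sum(n_less) / (n1 * n2)
  u <- sum(n2 - n_leq) / (n1 * n2)
  f - u
}

#' Compare two heteroplasmy spectra: effect size and Mann-Whitney test
#'
#' Returns the rank-biserial correlation difference together with the
#' two-sided Mann-Whitney U p-value (exact for small tie-free samples,
#' normal approximation with tie correction otherwise, as implemented by
#' [stats::wilcox.test()]). When the comparison belongs to a family of
#' `family_size` tests, a Bonferroni-adjusted p-value is also reported.
#'
#' @param g1,g2 non-empty numeric vectors or `cryptic_sfs` objects.
#' @param family_size number of comparisons in the family for Bonferroni
#'   adjustment (default 1).
#' @return List with `r`, `U` (the Mann-Whitney statistic for `g1`), `p`,
#'   and `p_bonferroni`.
#' @export
compare_sfs <- function(g1, g2, family_size = 1) {
  if (inherits(g1, "cryptic_sfs")) g1 <- g1$h
  if (inherits(g2, "cryptic_sfs")) g2 <- g2$h
  if (length(g1) == 0 || length(g2) == 0)
    stop("compare_sfs requires two non-empty sets")
  if (length(unique(c(g1, g2))) == 1L) {
    # fully degenerate: identical constant samples
    return(list(r = 0, U = length(g1) * length(g2) / 2, p = 1,
                p_bonferroni = 1))
  }
  wt <- suppressWarnings(wilcox.test(g1, g2, alternative = "two.sided"))
  list(r = rbc_difference(g1, g2),
       U = unname(wt$statistic),
       p = wt$p.value,
       p_bonferroni = min(1, wt$p.value * family_size))
}

#' Pairwise spectrum comparisons with Bonferroni adjustment
#'
#' Convenience wrapper applying [compare_sfs()] to every ordered pair of a
#' named list of heteroplasmy sets, with the family size equal to the number
#' of unordered pairs.
#'
#' @param groups named list of numeric vectors or `cryptic_sfs` objects.
#' @return data.frame with columns `group1`, `group2`, `r`, `U`, `p`,
#'   `p_bonferroni`.
#' @export
compare_sfs_groups <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2, !is.null(names(groups)))
  nm <- names(groups)
  pairs <- utils::combn(nm, 2)
  fam <- ncol(pairs)
  out <- lapply(seq_len(fam), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    cs <- compare_sfs(groups[[a]], groups[[b]], family_size = fam)
    data.frame(group1 = a, group2 = b, r = cs$r, U = cs$U, p = cs$p,
               p_bonferroni = cs$p_bonferroni)
  })
  do.call(rbind, out)
}

#' Opportunity counts from a pathology annotation table
#'
#' Counts the substitutions in the annotation universe that are synonymous
#' versus non-synonymous (low, high, or unscored non-synonymous classes),
#' providing the normalization for [dnds_test()].
#'
#' @param annotation data.frame with columns `pos`, `ref`, `alt`, `class`.
#' @return Named numeric vector `c(synonymous = ..., non_synonymous = ...)`.
#' @export
opportunity_counts <- function(annotation) {
  cls <- annotation$class
  c(synonymous = sum(cls == "synonymous"),
    non_synonymous = sum(cls %in% c("low", "high", "non-synonymous")))
}

#' dN/dS-style Fisher test on heteroplasmy-stratified counts
#'
#' Cross-classifies annotated variants by pathology class (synonymous vs
#' non-synonymous, the latter pooling low and high pathogenicity) and by
#' whether the heteroplasmy exceeds `floor`, and applies a two-sided exact
#' Fisher test to the 2x2 table. The non-synonymous/synonymous ratio among
#' variants above the floor is reported, normalized by the opportunity
#' counts of the annotation universe when supplied.
#'
#' @param vt an annotated, classified variant table.
#' @param scope which variants to test: `"cryptic"`, `"non-cryptic"`
#'   (shared) or `"all"` (cryptic + shared; common variants are always
#'   excluded from statistics).
#' @param floor heteroplasmy threshold for the above/below stratification
#'   (default 0.10).
#' @param opportunity optional named vector from [opportunity_counts()].
#' @return List with `table` (2x2 counts), `ratio` (opportunity-normalized
#'   when available, `NA` and `flagged = TRUE` when no synonymous variants
#'   were observed), `ratio_raw`, `p`, `flagged`.
#' @export
dnds_test <- function(vt, scope = c("cryptic", "non-cryptic", "all"),
                      floor = 0.10, opportunity = NULL) {
  scope <- match.arg(scope)
  rows <- switch(scope,
    "cryptic" = vt[vt$classification == "cryptic", , drop = FALSE],
    "non-cryptic" = vt[vt$classification == "shared", , drop = FALSE],
    "all" = vt[vt$classification %in% c("cryptic", "shared"), , drop = FALSE])
  cls <- ifelse(rows$pathology == "synonymous", "synonymous",
         ifelse(rows$pathology %in% c("low", "high", "non-synonymous"),
                "non_synonymous", NA))
  keep <- !is.na(cls)
  rows <- rows[keep, , drop = FALSE]
  cls <- cls[keep]
  above <- factor(rows$h > floor, levels = c(TRUE, FALSE))
  cls <- factor(cls, levels = c("non_synonymous", "synonymous"))
  tab <- table(cls, above)
  n_syn_above <- tab["synonymous", "TRUE"]
  n_ns_above <- tab["non_synonymous", "TRUE"]
  flagged <- n_syn_above == 0
  ratio_raw <- if (flagged) NA_real_ else n_ns_above / n_syn_above
  ratio <- if (!is.null(opportunity) && !flagged) {
    (n_ns_above / opportunity[["non_synonymous"]]) /
      (n_syn_above / opportunity[["synonymous"]])
  } else ratio_raw
  p <- if (all(rowSums(tab) > 0) && all(colSums(tab) > 0))
    fisher.test(tab)$p.value else NA_real_
  list(table = tab, ratio = unname(ratio), ratio_raw = ratio_raw,
       p = p, flagged = flagged)
}

#' Pseudobulk heteroplasmy and the invisibility of cryptic mutations
#'
#' Emulates a bulk experiment: for every distinct variant (donor, site, alt)
#' the pseudobulk heteroplasmy is the sum of its alternate reads over all
#' retained cells of the donor divided by the summed depth of those cells
#' at the site. Reports the fraction of variants whose pseudobulk
#' heteroplasmy falls below `bulk_cut` (and would therefore escape a bulk
#' experiment) and, among those, the fraction found in only a single cell.
#'
#' @param counts a [BaseCountMatrix][read_base_counts()] data.frame.
#' @param vt a variant table from the same cohort.
#' @param bulk_cut pseudobulk detectability threshold (default 0.005).
#' @param mask optional [qc_filter()] mask restricting to retained cells.
#' @return List with `variants` (data.frame: donor, pos, alt, pseudobulk_h,
#'   n_cells), `fraction_below`, `fraction_single_cell`.
#' @export
pseudobulk_spectrum <- function(counts, vt, bulk_cut = 0.005, mask = NULL) {
  if (!is.null(mask)) {
    keep_cells <- mask$cells$cell[mask$cells$retained]
    counts <- counts[counts$cell %in% keep_cells, , drop = FALSE]
    vt <- vt[vt$cell %in% keep_cells, , drop = FALSE]
  }
  if (nrow(vt) == 0)
    return(list(variants = data.frame(), fraction_below = NA_real_,
                fraction_single_cell = NA_real_))
  counts$depth <- counts$A + counts$C + counts$G + counts$T
  vars <- unique(vt[, c("donor", "pos", "alt")])
  res <- lapply(seq_len(nrow(vars)), function(i) {
    d <- vars$donor[i]; p <- vars$pos[i]; a <- vars$alt[i]
    sub <- counts[counts$donor == d & counts$pos == p, , drop = FALSE]
    alt_reads <- sum(sub[[a]])
    depth <- sum(sub$depth)
    n_cells <- sum(vt$donor == d & vt$pos == p & vt$alt == a)
    data.frame(donor = d, pos = p, alt = a,
               pseudobulk_h = if (depth > 0) alt_reads / depth else NA_real_,
               n_cells = n_cells)
  })
  res <- do.call(rbind, res)
  below <- res$pseudobulk_h < bulk_cut
  list(variants = res,
       fraction_below = mean(below, na.rm = TRUE),
       fraction_single_cell = if (any(below, na.rm = TRUE))
         mean(res$n_cells[which(below)] == 1) else NA_real_)
}

#' Per-cell homoplasmic mutation rate, normalized by bases observed
#'
#' For each retained cell, the number of cryptic mutations at heteroplasmy
#' `>= cut` divided by the number of positions passing depth quality control
#' in that cell.
#'
#' @param vt a classified variant table.
#' @param mask the [qc_filter()] mask used to call `vt`.
#' @param cut homoplasmy threshold (default 0.95).
#' @return List with `per_cell` (data.frame: cell, donor, n_homoplasmic,
#'   n_qualified, rate), `donor_means`, `cohort_mean`.
#' @export
homoplasmy_rate <- function(vt, mask, cut = 0.95) {
  cells <- mask$cells[mask$cells$retained, , drop = FALSE]
  if (nrow(cells) == 0) stop("no retained cells in mask")
  hom <- vt[vt$classification == "cryptic" & vt$h >= cut, , drop = FALSE]
  nh <- setNames(rep(0L, nrow(cells)), cells$cell)
  if (nrow(hom) > 0) {
    cnt <- table(hom$cell)
    hit <- intersect(names(cnt), names(nh))
    nh[hit] <- as.integer(cnt[hit])
  }
  per_cell <- data.frame(cell = cells$cell, donor = cells$donor,
                         n_homoplasmic = unname(nh[cells$cell]),
                         n_qualified = cells$n_qualified,
                         rate = unname(nh[cells$cell]) / cells$n_qualified,
                         row.names = NULL)
  donor_means <- tapply(per_cell$rate, per_cell$donor, mean)
  list(per_cell = per_cell,
       donor_means = donor_means,
       cohort_mean = mean(per_cell$rate))
}
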