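# Heteroplasmy calling and cryptic/shared/common classification from
# per-cell base counts.

#' Depth and cell-level quality control of a base-count matrix
#'
#' A (cell, site) pair qualifies when its total depth strictly exceeds
#' `min_depth` reads. A cell is retained when (a) it has at least
#' `min_positions` qualified positions and (b) the base-10 logarithm of its
#' qualified-position count lies within `sigma_mult` standard deviations of
#' the cohort mean of the same quantity (the log-normal outlier rule,
#' computed over cells satisfying (a); when that set has zero variance every
#' such cell is retained). Per-(donor, site) counts of qualifying retained
#' cells are recorded for later site exclusion.
#'
#' @param counts data.frame with columns `cell`, `donor`, `pos`, `A`, `C`,
#'   `G`, `T` (see [read_base_counts()]).
#' @param min_depth a position qualifies at depth strictly greater than this
#'   (default 200 reads).
#' @param min_positions minimum number of qualified positions for a cell to
#'   be retained (default 200).
#' @param sigma_mult width of the log-normal retention band in standard
#'   deviations (default 3).
#' @return An object of class `qc_mask`: list with `cells` (data.frame:
#'   cell, donor, n_qualified, log10_n, z, retained), `qualified`
#'   (data.frame of qualifying cell/pos pairs for retained cells),
#'   `donor_site` (data.frame: donor, pos, n_cells qualifying among
#'   retained cells) and the thresholds used.
#' @export
qc_filter <- function(counts, min_depth = 200, min_positions = 200,
                      sigma_mult = 3) {
  if (nrow(counts) == 0) stop("empty base-count matrix")
  depth <- counts$A + counts$C + counts$G + counts$T
  qual <- depth > min_depth
  cell_ids <- unique(counts$cell)
  nq <- tapply(qual, counts$cell, sum)
  nq <- setNames(as.integer(nq[cell_ids]), cell_ids)
  nq[is.na(nq)] <- 0L
  donor_of <- counts$donor[match(cell_ids, counts$cell)]
  eligible <- nq >= min_positions
  log_n <- ifelse(nq > 0, log10(nq), NA_real_)
  mu <- mean(log_n[eligible])
  s <- sd(log_n[eligible])
  z <- rep(NA_real_, length(cell_ids))
  if (any(eligible)) {
    if (is.na(s) || s == 0) {
      z[eligible] <- 0
    } else {
      z[eligible] <- (log_n[eligible] - mu) / s
    }
  }
  retained <- eligible & !is.na(z) & abs(z) <= sigma_mult
  cells <- data.frame(cell = cell_ids, donor = donor_of,
                      n_qualified = unname(nq), log10_n = unname(log_n),
                      z = z, retained = unname(retained), row.names = NULL)
  if (!any(retained))
    warning("qc_filter: no cells retained", call. = FALSE)
  keep <- qual & counts$cell %in% cell_ids[retained]
  qualified <- data.frame(cell = counts$cell[keep], donor = counts$donor[keep],
                          pos = counts$pos[keep], row.names = NULL)
  if (nrow(qualified) > 0) {
    ds <- aggregate(cell ~ donor + pos, data = qualified, FUN = length)
    names(ds)[names(ds) == "cell"] <- "n_cells"
  } else {
    ds <- data.frame(donor = character(0), pos = integer(0),
                     n_cells = integer(0))
  }
  structure(list(cells = cells, qualified = qualified, donor_site = ds,
                 min_depth = min_depth, min_positions = min_positions,
                 sigma_mult = sigma_mult),
            class = "qc_mask")
}

#' @export
print.qc_mask <- function(x, ...) {
  cat(sprintf("QC mask: %d/%d cells retained (depth > %g, >= %g positions, +/- %g SD log10)\n",
              sum(x$cells$retained), nrow(x$cells), x$min_depth,
              x$min_positions, x$sigma_mult))
  invisible(x)
}

#' Call per-cell heteroplasmic variants from base counts
#'
#' For every qualified (cell, site) pair of a retained cell and every
#' non-reference base `i` with at least one read, the heteroplasmy is the
#' read fraction `h_i = N_i / (N_A + N_C + N_G + N_T)`. Several alternate
#' bases at one site yield separate rows. No read deduplication is
#' performed.
#'
#' @param counts the base-count matrix the mask was computed from.
#' @param mask a [qc_filter()] mask.
#' @param reference reference bases: either a character vector named by
#'   position, or a data.frame with columns `pos` and `ref`.
#' @return A `VariantTable` data.frame: `cell`, `donor`, `pos`, `ref`,
#'   `alt`, `h`, `depth`, `alt_reads`.
#' @export
call_variants <- function(counts, mask, reference) {
  if (is.data.frame(reference))
    reference <- setNames(as.character(reference$ref),
                          as.character(reference$pos))
  if (is.null(names(reference)))
    names(reference) <- seq_along(reference)
  key_q <- paste(mask$qualified$cell, mask$qualified$pos)
  keep <- paste(counts$cell, counts$pos) %in% key_q
  cc <- counts[keep, , drop = FALSE]
  if (nrow(cc) == 0)
    return(empty_variant_table())
  ref <- reference[as.character(cc$pos)]
  if (anyNA(ref)) {
    bad <- unique(cc$pos[is.na(ref)])
    stop("reference base missing for site(s): ",
         paste(head(bad, 5), collapse = ", "))
  }
  depth <- cc$A + cc$C + cc$G + cc$T
  bases <- c("A", "C", "G", "T")
  out <- lapply(bases, function(b) {
    sel <- ref != b & cc[[b]] > 0
    if (!any(sel)) return(NULL)
    data.frame(cell = cc$cell[sel], donor = cc$donor[sel], pos = cc$pos[sel],
               ref = ref[sel], alt = b, h = cc[[b]][sel] / depth[sel],
               depth = depth[sel], alt_reads = cc[[b]][sel],
               row.names = NULL)
  })
  vt <- do.call(rbind, out)
  if (is.null(vt)) return(empty_variant_table())
  vt <- vt[order(vt$cell, vt$pos, vt$alt), , drop = FALSE]
  rownames(vt) <- NULL
  vt
}

empty_variant_table <- function() {
  data.frame(cell = character(0), donor = character(0), pos = integer(0),
             ref = character(0), alt = character(0), h = numeric(0),
             depth = numeric(0), alt_reads = numeric(0))
}

#' Classify called variants as cryptic, shared or common
#'
#' Applies, in order: (1) site exclusion -- variants at sites qualified in
#' fewer than `min_cells_per_site` retained cells of their donor are
#' dropped; (2) the common rule -- a (site, alt) substitution observed above
#' `cryptic_floor` in more than `common_donor_count` donors is labelled
#' `common` (common variants are retained in the table but excluded from
#' downstream statistics); (3) the cryptic rule -- a variant is `cryptic`
#' when its (site, alt) occurs above `cryptic_floor` in exactly one cell of
#' the donor, and that occurrence is this row; every other variant is
#' `shared`; (4) the report floor -- only rows with `h` strictly greater
#' than `report_floor` are kept. All floor comparisons are strict.
#'
#' @param vt a variant table from [call_variants()].
#' @param mask the [qc_filter()] mask used for calling.
#' @param cryptic_floor heteroplasmy above which a variant counts as an
#'   occurrence for the cryptic/common rules (default 0.05).
#' @param report_floor final reporting floor (default 0.10; lower it to
#'   0.05 for sparse low-coverage data).
#' @param common_donor_count a substitution in more than this many donors
#'   is common (default 3).
#' @param min_cells_per_site minimum retained cells covering a site within
#'   a donor (default 10).
#' @return The classified variant table with a `classification` column;
#'   attributes `report_floor` and `cryptic_floor` record the floors used.
#' @export
classify_variants <- function(vt, mask, cryptic_floor = 0.05,
                              report_floor = 0.10, common_donor_count = 3,
                              min_cells_per_site = 10) {
  known_donors <- unique(mask$cells$donor)
  if (!all(vt$donor %in% known_donors)) {
    bad <- setdiff(unique(vt$donor), known_donors)
    stop("unknown donor id(s): ", paste(bad, collapse = ", "))
  }
  # (1) site exclusion within donor
  ds <- mask$donor_site
  ok_key <- paste(ds$donor[ds$n_cells >= min_cells_per_site],
                  ds$pos[ds$n_cells >= min_cells_per_site])
  vt <- vt[paste(vt$donor, vt$pos) %in% ok_key, , drop = FALSE]
  if (nrow(vt) == 0) {
    vt$classification <- character(0)
    attr(vt, "report_floor") <- report_floor
    attr(vt, "cryptic_floor") <- cryptic_floor
    return(vt)
  }
  occ <- vt$h > cryptic_floor
  var_key <- paste(vt$pos, vt$alt)
  # (2) common rule: donors with an occurrence of this substitution
  donors_per_var <- tapply(vt$donor[occ], var_key[occ],
                           function(d) length(unique(d)))
  common_vars <- names(donors_per_var)[donors_per_var > common_donor_count]
  is_common <- var_key %in% common_vars
  # (3) cryptic rule: exactly one occurrence cell within the donor
  dv_key <- paste(vt$donor, var_key)
  cells_per_dv <- tapply(vt$cell[occ], dv_key[occ],
                         function(cl) length(unique(cl)))
  unique_dv <- names(cells_per_dv)[cells_per_dv == 1]
  is_cryptic <- !is_common & occ & dv_key %in% unique_dv
  vt$classification <- ifelse(is_common, "common",
                              ifelse(is_cryptic, "cryptic", "shared"))
  # (4) report floor
  vt <- vt[vt$h > report_floor, , drop = FALSE]
  rownames(vt) <- NULL
  attr(vt, "report_floor") <- report_floor
  attr(vt, "cryptic_floor") <- cryptic_floor
  vt
}

#' Annotate variants with pathology classes
#'
#' Joins the pathology class (`synonymous`, `low`, `high`, `noncoding`) on
#' (site, ref, alt); substitutions absent from the table are classed
#' `unknown`. For species without pathogenicity scores (e.g. mouse), set
#' `collapse = TRUE` to merge `low` and `high` into `non-synonymous`.
#'
#' @param vt a variant table.
#' @param annotation data.frame with columns `pos`, `ref`, `alt`, `class`.
#' @param collapse collapse pathogenicity grades into a binary
#'   synonymous/non-synonymous annotation (default `FALSE`).
#' @return `vt` with a `pathology` column added.
#' @export
annotate_variants <- function(vt, annotation, collapse = FALSE) {
  key_a <- paste(annotation$pos, annotation$ref, annotation$alt)
  if (anyDuplicated(key_a)) {
    dup <- key_a[duplicated(key_a)]
    cls <- tapply(annotation$class, key_a, function(x) length(unique(x)))
    if (any(cls[dup] > 1))
      stop("contradictory duplicate annotation rows for: ",
           paste(unique(dup[cls[dup] > 1]), collapse = ", "))
    annotation <- annotation[!duplicated(key_a), , drop = FALSE]
    key_a <- key_a[!duplicated(key_a)]
  }
  idx <- match(paste(vt$pos, vt$ref, vt$alt), key_a)
  cls <- as.character(annotation$class)[idx]
  cls[is.na(cls)] <- "unknown"
  if (collapse)
    cls[cls %in% c("low", "high")] <- "non-synonymous"
  vt$pathology <- cls
  vt
}
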