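# End-to-end pipeline: qc -> call -> classify -> annotate -> cSFS ->
# statistics -> (optional) coalescent fit -> prediction, with a
# machine-readable run report.

#' Pipeline configuration
#'
#' A single structured configuration drives a reproducible run: input
#' paths, thresholds, model settings and one master seed. Configurations
#' round-trip through YAML ([read_pipeline_config()]).
#'
#' @param counts,metadata,annotation,reference input file paths
#'   (annotation may be `NA` to skip pathology annotation).
#' @param out output directory.
#' @param min_depth,min_positions,sigma_mult see [qc_filter()].
#' @param cryptic_floor,report_floor,common_donor_count,min_cells_per_site
#'   see [classify_variants()].
#' @param homoplasmy_cut,bins see [build_csfs()].
#' @param bulk_cut see [pseudobulk_spectrum()].
#' @param fit run the coalescent fit per donor (logical).
#' @param N_assumed assumed copy number for rate conversion.
#' @param collapse_pathology collapse low/high into non-synonymous (for
#'   species without pathogenicity scores).
#' @param seed master seed.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(counts, metadata, annotation = NA,
                            reference, out,
                            min_depth = 200, min_positions = 200,
                            sigma_mult = 3, cryptic_floor = 0.05,
                            report_floor = 0.10, common_donor_count = 3,
                            min_cells_per_site = 10, homoplasmy_cut = 0.95,
                            bins = 20, bulk_cut = 0.005, fit = FALSE,
                            N_assumed = 1000, collapse_pathology = FALSE,
                            seed = 1L) {
  cfg <- list(paths = list(counts = counts, metadata = metadata,
                           annotation = annotation, reference = reference,
                           out = out),
              thresholds = list(min_depth = min_depth,
                                min_positions = min_positions,
                                sigma_mult = sigma_mult,
                                cryptic_floor = cryptic_floor,
                                report_floor = report_floor,
                                common_donor_count = common_donor_count,
                                min_cells_per_site = min_cells_per_site,
                                homoplasmy_cut = homoplasmy_cut,
                                bins = bins, bulk_cut = bulk_cut),
              model = list(fit = fit, N_assumed = N_assumed,
                           collapse_pathology = collapse_pathology,
                           seed = as.integer(seed)))
  validate_pipeline_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_pipeline_config <- function(cfg) {
  th <- cfg$thresholds
  stopifnot(th$min_depth >= 0, th$min_positions >= 0, th$sigma_mult > 0,
            th$cryptic_floor >= 0, th$cryptic_floor < 1,
            th$report_floor >= 0, th$report_floor < 1,
            th$common_donor_count >= 1, th$min_cells_per_site >= 1,
            th$homoplasmy_cut > th$report_floor, th$homoplasmy_cut <= 1,
            th$bins >= 1, th$bulk_cut > 0)
  invisible(cfg)
}

#' Read and write pipeline configurations as YAML
#' @param path YAML file path.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_pipeline_config(cfg)
  structure(cfg, class = "pipeline_config")
}

#' @rdname read_pipeline_config
#' @param config a `pipeline_config` object.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes quality control, variant calling, classification, optional
#' pathology annotation, per-donor cryptic SFS construction, summary
#' statistics (mutation load, pseudobulk spectrum, homoplasmy rates,
#' pairwise donor comparisons) and, when requested, the per-donor
#' coalescent fit. All artifacts are written under the configured output
#' directory together with a machine-readable JSON run report recording
#' counts in and out of every stage, the thresholds, and the seed. Runs
#' are deterministic given an identical configuration.
#'
#' @param config a [pipeline_config()] object (or path to its YAML form).
#' @return The run report, invisibly (a named list).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  validate_pipeline_config(config)
  th <- config$thresholds
  out_dir <- config$paths$out
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  metadata <- stage("read_metadata", read_metadata(config$paths$metadata))
  counts <- stage("read_counts",
                  read_base_counts(config$paths$counts, metadata))
  reference <- stage("read_reference",
                     read_reference(config$paths$reference))
  annotation <- NULL
  if (!is.null(config$paths$annotation) && !is.na(config$paths$annotation))
    annotation <- stage("read_annotation",
                        read_annotation(config$paths$annotation))

  report <- list(seed = config$model$seed, thresholds = th,
                 n_count_rows = nrow(counts),
                 n_cells_in = length(unique(counts$cell)))

  mask <- stage("qc", qc_filter(counts, th$min_depth, th$min_positions,
                                th$sigma_mult))
  report$n_cells_retained <- sum(mask$cells$retained)
  write.table(mask$cells, file.path(out_dir, "qc_cells.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  vt <- stage("call", call_variants(counts, mask, reference))
  report$n_variants_called <- nrow(vt)

  vt <- stage("classify",
              classify_variants(vt, mask, th$cryptic_floor,
                                th$report_floor, th$common_donor_count,
                                th$min_cells_per_site))
  report$n_variants_retained <- nrow(vt)
  report$n_by_class <- as.list(table(vt$classification))

  if (!is.null(annotation)) {
    vt <- stage("annotate",
                annotate_variants(vt, annotation,
                                  collapse = config$model$collapse_pathology))
  } else {
    vt$pathology <- "unknown"
  }
  write_variant_table(vt, file.path(out_dir, "variants.tsv"), "tsv")
  write_variant_table(vt, file.path(out_dir, "variants.vcf"), "vcf")

  donors <- sort(unique(mask$cells$donor[mask$cells$retained]))
  sfs_list <- list()
  for (d in donors) {
    if (!d %in% vt$donor) next
    sfs <- stage("csfs", build_csfs(vt, d, bins = th$bins,
                                    homoplasmy_cut = th$homoplasmy_cut,
                                    floor = th$report_floor))
    sfs_list[[d]] <- sfs
    write_csfs(sfs, file.path(out_dir, sprintf("csfs_%s.tsv", d)))
  }
  report$n_donors_with_csfs <- sum(vapply(sfs_list, function(s) !s$empty,
                                          logical(1)))

  load <- stage("load", mutation_load(vt, t = th$report_floor))
  write.table(load, file.path(out_dir, "mutation_load.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  pb <- stage("pseudobulk",
              pseudobulk_spectrum(counts, vt, th$bulk_cut, mask))
  report$pseudobulk_fraction_below <- pb$fraction_below

  hr <- stage("homoplasmy", homoplasmy_rate(vt, mask, th$homoplasmy_cut))
  write.table(hr$per_cell, file.path(out_dir, "homoplasmy_rate.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  report$cohort_homoplasmy_rate <- hr$cohort_mean

  nonempty <- Filter(function(s) !s$empty, sfs_list)
  if (length(nonempty) >= 2) {
    cmp <- stage("compare",
                 compare_sfs_groups(lapply(nonempty, function(s) s$h)))
    write.table(cmp, file.path(out_dir, "comparisons.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }

  if (isTRUE(config$model$fit)) {
    fits <- list()
    for (d in names(nonempty)) {
      n_cells_d <- sum(mask$cells$retained & mask$cells$donor == d)
      fit <- stage("fit", mito_fit(nonempty[[d]]$h, n_cells_d,
                                   floor = th$report_floor,
                                   homoplasmy_cut = th$homoplasmy_cut,
                                   bins = th$bins,
                                   seed = config$model$seed))
      fits[[d]] <- fit
      smry <- summary(fit, N = config$model$N_assumed)
      write.table(
        data.frame(donor = d, W_map = fit$map[["W"]],
                   W_lo = fit$ci["W", 1], W_hi = fit$ci["W", 2],
                   theta_map = fit$map[["theta"]],
                   theta_lo = fit$ci["theta", 1],
                   theta_hi = fit$ci["theta", 2], nu = smry$nu),
        file.path(out_dir, sprintf("fit_%s.tsv", d)), sep = "\t",
        quote = FALSE, row.names = FALSE)
      write.table(fit$samples,
                  file.path(out_dir, sprintf("posterior_%s.tsv", d)),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    report$fitted_donors <- names(fits)
  }

  jsonlite::write_json(report, file.path(out_dir, "run_report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(report)
}

#' Simulate a synthetic cohort and write its pipeline inputs
#'
#' Generates a cohort from a [cohort_config()], renders base counts, and
#' writes `counts.tsv`, `metadata.tsv`, `reference.tsv`, `annotation.tsv`
#' (over the cohort's substitution universe) and `truth.tsv` into a
#' directory, ready for [run_pipeline()].
#'
#' @param config a [cohort_config()] object.
#' @param out output directory.
#' @return Invisibly, a list with the `true_cohort` and the file paths.
#' @export
simulate_to_dir <- function(config, out) {
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  truth <- generate_cohort(config)
  counts <- render_base_counts(truth, seed = config$seed + 1L)
  paths <- list(counts = file.path(out, "counts.tsv"),
                metadata = file.path(out, "metadata.tsv"),
                reference = file.path(out, "reference.tsv"),
                annotation = file.path(out, "annotation.tsv"),
                truth = file.path(out, "truth.tsv"))
  write_base_counts(counts, paths$counts)
  write_metadata(truth$cells, paths$metadata)
  write_reference(truth$reference, paths$reference)
  universe <- substitution_universe(truth$reference,
                                    sort(unique(counts$pos)))
  annotation <- make_annotation_table(universe, seed = config$seed + 2L)
  write_annotation(annotation, paths$annotation)
  write.table(truth$mutations, paths$truth, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(list(truth = truth, paths = paths))
}
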