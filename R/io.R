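# Plain-text readers and writers for the pipeline's tabular formats.

req_cols <- function(df, cols, what, path) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(sprintf("%s file '%s' is missing column(s): %s", what, path,
                 paste(miss, collapse = ", ")))
}

#' Read a base-count matrix from tab-separated text
#'
#' Expects columns `cell`, `pos` (1-based mtDNA coordinate), `A`, `C`,
#' `G`, `T`. A `donor` column is taken from the file when present,
#' otherwise joined from the metadata table.
#'
#' @param path counts file path.
#' @param metadata optional metadata data.frame (or path) with columns
#'   `cell`, `donor` (and typically `age_years`, `species`).
#' @return A base-count data.frame with a `donor` column.
#' @export
read_base_counts <- function(path, metadata = NULL) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  req_cols(df, c("cell", "pos", "A", "C", "G", "T"), "base-count", path)
  num <- c("pos", "A", "C", "G", "T")
  for (col in num) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    if (anyNA(v) & !anyNA(df[[col]])) {
      bad <- which(is.na(v) & !is.na(df[[col]]))
      stop(sprintf("malformed numeric value in '%s', column %s, line(s) %s",
                   path, col, paste(head(bad + 1, 5), collapse = ", ")))
    }
    df[[col]] <- v
  }
  if (any(df[num] < 0, na.rm = TRUE))
    stop("negative counts in ", path)
  if (!"donor" %in% names(df)) {
    if (is.null(metadata))
      stop("counts file has no donor column and no metadata was supplied")
    if (is.character(metadata)) metadata <- read_metadata(metadata)
    df$donor <- metadata$donor[match(df$cell, metadata$cell)]
    if (anyNA(df$donor))
      stop("cells without donor metadata: ",
           paste(head(unique(df$cell[is.na(df$donor)]), 5), collapse = ", "))
  }
  df
}

#' @rdname read_base_counts
#' @param counts a base-count data.frame.
#' @export
write_base_counts <- function(counts, path) {
  write.table(counts[, c("cell", "pos", "A", "C", "G", "T")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write donor metadata (cell, donor, age_years, species)
#' @param path file path.
#' @export
read_metadata <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  req_cols(df, c("cell", "donor"), "metadata", path)
  df
}

#' @rdname read_metadata
#' @param metadata data.frame with at least `cell` and `donor`.
#' @export
write_metadata <- function(metadata, path) {
  write.table(metadata, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write pathology annotation tables (pos, ref, alt, class)
#' @param path file path.
#' @export
read_annotation <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  req_cols(df, c("pos", "ref", "alt", "class"), "annotation", path)
  df
}

#' @rdname read_annotation
#' @param annotation data.frame with `pos`, `ref`, `alt`, `class`.
#' @export
write_annotation <- function(annotation, path) {
  write.table(annotation, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write reference bases as tab-separated (pos, ref)
#' @param path file path.
#' @export
read_reference <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  req_cols(df, c("pos", "ref"), "reference", path)
  setNames(as.character(df$ref), as.character(df$pos))
}

#' @rdname read_reference
#' @param reference character vector of bases (named by position, or
#'   positional).
#' @export
write_reference <- function(reference, path) {
  pos <- if (is.null(names(reference))) seq_along(reference)
         else names(reference)
  write.table(data.frame(pos = pos, ref = as.character(reference)), path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a variant table as tab-separated text or minimal VCF
#'
#' The tsv format round-trips losslessly through
#' [read_variant_table()]. The VCF output is a minimal VCF 4.2 file
#' (CHROM `chrM`, POS, REF, ALT) with one sample column per cell carrying
#' `AF` (heteroplasmy) and `DP` (depth).
#'
#' @param vt a variant table.
#' @param path output path.
#' @param format `"tsv"` or `"vcf"`.
#' @export
write_variant_table <- function(vt, path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  if (format == "tsv") {
    write.table(vt, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  cells <- sort(unique(vt$cell))
  hdr <- c("##fileformat=VCFv4.2",
           "##contig=<ID=chrM>",
           "##FORMAT=<ID=AF,Number=1,Type=Float,Description=\"Allele fraction (heteroplasmy)\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", cells), collapse = "\t"))
  key <- paste(vt$pos, vt$ref, vt$alt)
  uq <- !duplicated(key)
  ord <- order(vt$pos[uq], vt$alt[uq])
  sites <- vt[uq, , drop = FALSE][ord, , drop = FALSE]
  body <- vapply(seq_len(nrow(sites)), function(i) {
    rows <- vt[key == paste(sites$pos[i], sites$ref[i], sites$alt[i]), ,
               drop = FALSE]
    geno <- setNames(rep(".", length(cells)), cells)
    geno[rows$cell] <- sprintf("%.6g:%d", rows$h, as.integer(rows$depth))
    paste(c("chrM", sites$pos[i], ".", sites$ref[i], sites$alt[i], ".",
            "PASS", ".", "AF:DP", geno), collapse = "\t")
  }, "")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_variant_table
#' @export
read_variant_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  req_cols(df, c("cell", "donor", "pos", "ref", "alt", "h", "depth"),
           "variant", path)
  df
}

#' Write a cryptic SFS: binned histogram plus the raw heteroplasmy list
#'
#' @param sfs a `cryptic_sfs` object.
#' @param path output path for the binned table (`bin_left`, `bin_right`,
#'   `count`, `density`); the raw list goes to `<path>.raw.tsv`.
#' @export
write_csfs <- function(sfs, path) {
  write.table(as.data.frame(sfs), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(data.frame(h = sfs$h), paste0(path, ".raw.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}
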