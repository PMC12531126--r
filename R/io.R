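# Readers and writers for the pipeline's tab-delimited interchange formats.
# One row per genetic alteration per sample; missing numeric cells are "NA".

segment_cols <- c(
  "patient", "sample", "chrom", "start", "end", "type",
  "Nt", "NA", "NB", "Np", "log2R", "mBAF", "MSF", "MCF", "clonal",
  "gene", "hgvs"
)
# internal names: the "NA" column is stored as "NA." to stay a legal R name
segment_cols_internal <- sub("^NA$", "NA.", segment_cols)

empty_segment_table <- function(n = 0) {
  df <- data.frame(
    patient = character(n), sample = character(n), chrom = character(n),
    start = integer(n), end = integer(n), type = character(n),
    Nt = integer(n), NA. = integer(n), NB = integer(n), Np = integer(n),
    log2R = NA_real_[rep(1, n)], mBAF = NA_real_[rep(1, n)],
    MSF = NA_real_[rep(1, n)], MCF = NA_real_[rep(1, n)],
    clonal = logical(n), gene = character(n), hgvs = character(n),
    stringsAsFactors = FALSE
  )
  if (n == 0) df$clonal <- logical(0)
  df
}

#' Read a per-sample segment table
#'
#' Tab-delimited, one row per alteration per sample, with columns
#' `patient, sample, chrom, start, end, type, Nt, NA, NB, Np, log2R, mBAF,
#' MSF, MCF, clonal, gene, hgvs`. `type` is one of `gain`, `loss`, `cnni`,
#' `snv`; coordinates are 1-based inclusive on hg38-named chromosomes.
#' The `NA` column (A-allele count) is renamed `NA.` internally.
#'
#' @param path File path.
#' @return Data frame with the columns above.
#' @export
read_segment_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = TRUE,
                          na.strings = "NA")
  missing <- setdiff(segment_cols_internal, names(df))
  if (length(missing)) {
    stop_ct(paste0("segment table lacks columns: ",
                   paste(missing, collapse = ", ")), "schema_error")
  }
  df <- df[segment_cols_internal]
  df$clonal <- as.logical(df$clonal)
  bad <- which(df$end < df$start)
  if (length(bad)) {
    stop_ct(paste0("end < start on rows: ", paste(bad, collapse = ", ")),
            "schema_error")
  }
  df
}

#' Write a segment table
#'
#' @param df Segment data frame (internal layout of [read_segment_table()]).
#' @param path Output path.
#' @export
write_segment_table <- function(df, path) {
  out <- df[segment_cols_internal]
  names(out) <- segment_cols
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

variant_cols <- c(
  "patient", "sample", "caller", "chrom", "pos", "ref", "alt",
  "vaf_t", "vaf_n", "dp_t", "dp_n", "mapq", "passed_internal",
  "in_pon", "in_popdb", "gene", "annotation"
)

#' Read a flat multi-caller variant table
#'
#' Tab-delimited with columns
#' `patient, sample, caller, chrom, pos, ref, alt, vaf_t, vaf_n, dp_t, dp_n,
#' mapq, passed_internal, in_pon, in_popdb, gene, annotation`. Rows are one
#' call by one caller in one sample. Population-database and
#' panel-of-normals membership are boolean columns (looked up upstream).
#'
#' This flat table is the supported variant interface; per-caller VCFs are
#' deliberately not parsed here because each caller encodes VAF/DP
#' differently — export calls to this layout first.
#'
#' @param path File path.
#' @return Data frame of variant calls.
#' @export
read_variant_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, na.strings = "NA")
  missing <- setdiff(variant_cols, names(df))
  if (length(missing)) {
    stop_ct(paste0("variant table lacks columns: ",
                   paste(missing, collapse = ", ")), "schema_error")
  }
  for (col in c("passed_internal", "in_pon", "in_popdb")) {
    df[[col]] <- as.logical(df[[col]])
  }
  df[variant_cols]
}

#' @rdname read_variant_table
#' @param df Variant data frame.
#' @export
write_variant_table <- function(df, path) {
  utils::write.table(df[variant_cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a BED file of targeted regions
#'
#' Standard 0-based half-open BED (first three columns used). Returns a
#' [GenomicRanges::GRanges] in 1-based inclusive coordinates.
#'
#' @param path File path.
#' @return `GRanges` of target intervals.
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 3) stop_ct("BED needs >= 3 columns", "schema_error")
  GenomicRanges::GRanges(
    seqnames = df[[1]],
    ranges = IRanges::IRanges(start = df[[2]] + 1L, end = df[[3]])
  )
}

metadata_cols <- c("patient", "sample", "site", "class", "timepoint")

#' Read sample metadata
#'
#' Tab-delimited with columns `patient, sample, site, class, timepoint`;
#' `class` is one of `primary`, `lymph-node`, `distant`, `relapse`; `site`
#' is an anatomical label (samples sharing a site string are treated as one
#' anatomical location).
#'
#' @param path File path.
#' @return Data frame of sample metadata.
#' @export
read_metadata <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  missing <- setdiff(metadata_cols, names(df))
  if (length(missing)) {
    stop_ct(paste0("metadata lacks columns: ",
                   paste(missing, collapse = ", ")), "schema_error")
  }
  bad <- setdiff(unique(df$class),
                 c("primary", "lymph-node", "distant", "relapse"))
  if (length(bad)) {
    stop_ct(paste0("unknown sample classes: ", paste(bad, collapse = ", ")),
            "schema_error")
  }
  df[metadata_cols]
}
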