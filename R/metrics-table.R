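# Per-sample metric panel, in table-column order.
sample_metric_names <- function() {
  c("depth", "ref_count", "alt_count", "other_count", "vaf",
    "median_bq_alt", "median_bq_ref", "median_mq_alt", "median_mq_all",
    "alt_fwd", "alt_rev", "ref_fwd", "ref_rev",
    "median_dist_readend_alt", "mad_pos_alt", "softclip_frac_alt",
    "mean_excess_nm_alt", "mq0_frac", "near_indel_frac",
    "improper_pair_frac_alt")
}

#' Metrics table column names
#'
#' The schema of the per-variant metrics table: the site key (`contig`,
#' `pos`, `ref`, `alt`) followed by the full metric panel for the tumor and
#' then the normal sample (`tumor_*`, `normal_*`).
#'
#' @return Character vector of column names.
#' @export
metrics_columns <- function() {
  c("contig", "pos", "ref", "alt",
    paste0("tumor_", sample_metric_names()),
    paste0("normal_", sample_metric_names()))
}

as_metrics_table <- function(df) {
  stopifnot(identical(names(df), metrics_columns()))
  rownames(df) <- NULL
  structure(df, class = c("somafilt_metrics", "data.frame"))
}

#' Write / read a metrics table
#'
#' The stage-one metric panel is persisted as gzip-compressed tab-delimited
#' text with a header row and the literal string `NA` as the missing-value
#' sentinel (e.g. alt-conditioned medians at sites with no alt reads).
#' A written table re-reads losslessly well beyond 6 significant figures.
#'
#' @param table A metrics table (`somafilt_metrics`).
#' @param path Destination path (conventionally `*.tsv.gz`).
#' @return `write_metrics_table()`: `path`, invisibly.
#'   `read_metrics_table()`: the table.
#' @export
write_metrics_table <- function(table, path) {
  stopifnot(inherits(table, "somafilt_metrics"))
  con <- gzfile(path, open = "wt")
  on.exit(close(con))
  utils::write.table(table, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_metrics_table
#' @details `read_metrics_table()` refuses tables whose header does not match
#'   the current schema (for example after a package upgrade that changed the
#'   panel): such caches are stale and must be recomputed.
#' @export
read_metrics_table <- function(path) {
  if (!file.exists(path)) stop("metrics table not found: ", path)
  con <- gzfile(path, open = "rt")
  hdr <- strsplit(readLines(con, n = 1L), "\t", fixed = TRUE)[[1]]
  close(con)
  if (!identical(hdr, metrics_columns()))
    stop("stale metrics table '", path, "': header does not match ",
         somafilt_version(),
         "; delete the cache and recompute the metrics stage", call. = FALSE)
  df <- utils::read.delim(gzfile(path), header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  df$contig <- as.character(df$contig)
  df$ref <- as.character(df$ref)
  df$alt <- as.character(df$alt)
  for (cn in setdiff(names(df), c("contig", "ref", "alt")))
    df[[cn]] <- as.numeric(df[[cn]])
  df$pos <- as.integer(df$pos)
  as_metrics_table(df)
}
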