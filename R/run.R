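#' Run the full filtering pipeline
#'
#' Wires the two stages together: computes (or reuses from cache) the
#' per-variant metric panel from the tumor/normal BAM pair, applies the
#' configured filters, and writes all outputs into `out_dir`:
#' \itemize{
#'   \item `filtered.vcf` -- the annotated VCF (FILTER column set);
#'   \item `per_variant_results.tsv` -- one row per candidate allele, one
#'     column per applied filter plus `overall`;
#'   \item `filter_summary.tsv` / `filter_summary.png` -- pass/fail counts;
#'   \item `metrics.tsv.gz` -- the full metrics table;
#'   \item `somafilt.log` -- timestamped log with the tool version, preset
#'     label, every applied threshold and cache-reuse statistics;
#'   \item `metrics_cache/` -- resumable per-chunk metric shards.
#' }
#'
#' @param tumor_bam,normal_bam Coordinate-sorted BAMs; missing `.bai`
#'   indexes are built if possible.
#' @param vcf Candidate VCF from any somatic caller.
#' @param out_dir Output directory (created if absent); all outputs are
#'   namespaced here, never written alongside the inputs.
#' @param filter_file Optional user filter configuration (tab-delimited);
#'   mutually exclusive with `icgc`.
#' @param icgc If `TRUE`, apply the ICGC-style preset instead of the
#'   default preset.
#' @param jobs Worker processes for the metrics stage (results are
#'   independent of this value).
#' @param chunk_size Variants per metric cache chunk.
#' @param pass_only If `TRUE`, the output VCF contains only PASS records.
#' @return Invisibly, a list with the output `paths`, the applied `config`,
#'   the `metrics` table, the `verdicts` and the filter `summary`.
#' @export
somafilt_run <- function(tumor_bam, normal_bam, vcf, out_dir,
                         filter_file = NULL, icgc = FALSE, jobs = 1L,
                         chunk_size = 1000L, pass_only = FALSE) {
  if (!is.null(filter_file) && isTRUE(icgc))
    stop("usage error: --filters and --icgc are mutually exclusive",
         call. = FALSE)
  for (f in c(tumor_bam, normal_bam, vcf))
    if (!file.exists(f)) stop("input not found: ", f, call. = FALSE)
  if (!is.null(filter_file) && !file.exists(filter_file))
    stop("input not found: ", filter_file, call. = FALSE)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  log_con <- log_open(file.path(out_dir, "somafilt.log"))
  on.exit(close(log_con))
  log_line(log_con, "INFO", somafilt_version())

  for (bam in c(tumor_bam, normal_bam)) {
    if (!file.exists(paste0(bam, ".bai")) &&
        !file.exists(sub("\\.bam$", ".bai", bam))) {
      log_line(log_con, "INFO", paste("building missing index for", bam))
      tryCatch(Rsamtools::indexBam(bam),
               error = function(e)
                 stop("cannot index BAM '", bam, "': ",
                      conditionMessage(e), call. = FALSE))
    }
  }

  config <- if (!is.null(filter_file)) load_filter_config(filter_file)
            else if (isTRUE(icgc)) icgc_preset()
            else default_preset()
  log_line(log_con, "INFO", paste("filter preset:", config$preset))
  for (i in seq_len(nrow(config$entries)))
    log_line(log_con, "INFO",
             sprintf("filter %s threshold=%s", config$entries$name[i],
                     format(config$entries$threshold[i], trim = TRUE)))

  metrics <- run_metrics_stage(vcf, tumor_bam, normal_bam,
                               cache_dir = file.path(out_dir, "metrics_cache"),
                               jobs = jobs, chunk_size = chunk_size)
  log_line(log_con, "INFO",
           sprintf("metrics: %d variants; %d/%d chunks reused from cache",
                   nrow(metrics), attr(metrics, "chunks_reused"),
                   attr(metrics, "chunks_total")))
  write_metrics_table(metrics, file.path(out_dir, "metrics.tsv.gz"))

  verdicts <- apply_filters(config, metrics)
  res_path <- file.path(out_dir, "per_variant_results.tsv")
  utils::write.table(as.data.frame(verdicts), res_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  summ <- summarize_and_plot(verdicts, out_dir)
  log_line(log_con, "INFO",
           sprintf("filtering: %d/%d variants pass all filters",
                   summ$overall_pass, summ$total))

  candidates <- read_candidate_variants(vcf)
  vcf_out <- file.path(out_dir, "filtered.vcf")
  write_filtered_vcf(candidates, verdicts, config, vcf_out,
                     pass_only = pass_only)
  log_line(log_con, "INFO", paste("wrote", vcf_out))

  invisible(list(
    paths = list(vcf = vcf_out, results = res_path, summary = summ$tsv,
                 plot = summ$plot, log = file.path(out_dir, "somafilt.log"),
                 metrics = file.path(out_dir, "metrics.tsv.gz")),
    config = config, metrics = metrics, verdicts = verdicts,
    summary = summ$summary))
}
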