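#' The filter catalogue
#'
#' Every filter somafilt knows about, with the metric it reads, its direction
#' and its missing-value policy. Filter names are the stable public API used
#' in configuration files and VCF FILTER annotations.
#'
#' Directions: a `min` filter fails a variant when the metric is strictly
#' below the threshold; a `max` filter when it is strictly above. Equality
#' always passes, in both directions -- a single global tie-break rule that
#' keeps configurations interpretable.
#'
#' Missing values: metrics conditioned on alternate-allele reads are `NA`
#' when a sample has no alt reads at the site. For somatic calling the
#' absence of any alt evidence is itself disqualifying, so alt-conditioned
#' filters default to `fail_on_na`. The strand filter is instead marked
#' `not_applicable` below 10 alt reads, where a minor-strand fraction is
#' too noisy to judge.
#'
#' @return A data frame with columns `name`, `metric`, `direction`
#'   (`min`/`max`), `na_policy` (`fail_on_na`/`pass_on_na`), `description`,
#'   `default` and `icgc` (the two preset thresholds).
#' @seealso [default_preset()], [icgc_preset()], [evaluate_filter()]
#' @export
filter_catalogue <- function() {
  cat <- rbind(
    c("min_depth_tumor", "tumor_depth", "min", "fail_on_na",
      "Minimum read depth in the tumor", "10", "10"),
    c("min_depth_normal", "normal_depth", "min", "fail_on_na",
      "Minimum read depth in the normal", "10", "10"),
    c("min_alt_count_tumor", "tumor_alt_count", "min", "fail_on_na",
      "Minimum alt-supporting reads in the tumor", "3", "3"),
    c("min_vaf_tumor", "tumor_vaf", "min", "fail_on_na",
      "Minimum tumor variant allele frequency", "0.05", "0.10"),
    c("max_vaf_normal", "normal_vaf", "max", "fail_on_na",
      "Maximum normal variant allele frequency", "0.03", "0.02"),
    c("max_alt_count_normal", "normal_alt_count", "max", "fail_on_na",
      "Maximum alt-supporting reads in the normal", "1", "1"),
    c("min_median_bq_alt_tumor", "tumor_median_bq_alt", "min", "fail_on_na",
      "Minimum median base quality of tumor alt reads", "30", "30"),
    c("min_median_mq_alt_tumor", "tumor_median_mq_alt", "min", "fail_on_na",
      "Minimum median mapping quality of tumor alt reads", "40", "40"),
    c("strand_minor_frac_alt_tumor", "tumor_strand_minor_frac_alt", "min",
      "fail_on_na",
      "Minimum minor-strand fraction of tumor alt reads (needs >=10 alt reads)",
      "0.05", "0.05"),
    c("min_median_dist_readend_alt_tumor", "tumor_median_dist_readend_alt",
      "min", "fail_on_na",
      "Minimum median distance of the variant from the nearer read end",
      "10", "10"),
    c("min_mad_pos_alt_tumor", "tumor_mad_pos_alt", "min", "fail_on_na",
      "Minimum MAD of variant position within tumor alt reads", "3", "3"),
    c("max_softclip_frac_alt_tumor", "tumor_softclip_frac_alt", "max",
      "fail_on_na",
      "Maximum fraction of tumor alt reads carrying soft-clips", "0.30", "0.30"),
    c("max_excess_nm_alt_tumor", "tumor_mean_excess_nm_alt", "max",
      "fail_on_na",
      "Maximum mean excess edit distance (NM-1) of tumor alt reads",
      "2.0", "2.0"),
    c("max_mq0_frac_tumor", "tumor_mq0_frac", "max", "fail_on_na",
      "Maximum fraction of tumor reads with mapping quality zero",
      "0.10", "0.05"),
    c("max_near_indel_frac_tumor", "tumor_near_indel_frac", "max",
      "fail_on_na",
      "Maximum fraction of tumor reads with an indel within 5 bp of the site",
      "0.30", "0.30"),
    c("max_improper_pair_frac_alt_tumor", "tumor_improper_pair_frac_alt",
      "max", "fail_on_na",
      "Maximum fraction of tumor alt reads not in a proper pair",
      "0.50", "0.50"))
  out <- data.frame(cat, stringsAsFactors = FALSE)
  names(out) <- c("name", "metric", "direction", "na_policy", "description",
                  "default", "icgc")
  out$default <- as.numeric(out$default)
  out$icgc <- as.numeric(out$icgc)
  out
}

new_filter_config <- function(names, thresholds, preset) {
  structure(list(
    entries = data.frame(name = names, threshold = as.numeric(thresholds),
                         stringsAsFactors = FALSE),
    preset = preset),
    class = "somafilt_config")
}

#' Built-in filter presets
#'
#' `default_preset()` returns the package's own filter set; `icgc_preset()`
#' returns thresholds following the ICGC benchmarking recommendations, which
#' tighten the minimum tumor VAF, the tolerated normal VAF and the tolerated
#' mapping-quality-zero fraction. Both tables are also shipped as editable
#' tab-delimited files (see `system.file("extdata", package = "somafilt")`)
#' so users can copy and adapt them.
#'
#' @return A `somafilt_config`: a list with `entries` (data frame of `name`,
#'   `threshold`, in catalogue order) and `preset` label.
#' @export
default_preset <- function() {
  cat <- filter_catalogue()
  new_filter_config(cat$name, cat$default, "default")
}

#' @rdname default_preset
#' @export
icgc_preset <- function() {
  cat <- filter_catalogue()
  new_filter_config(cat$name, cat$icgc, "icgc")
}

#' Load a filter configuration file
#'
#' Reads a two-column tab-delimited file of `filter_name<TAB>threshold`.
#' Lines starting with `#` are comments. Only the filters listed are applied,
#' in file order.
#'
#' @param path Path to the configuration file.
#' @return A `somafilt_config` with `preset = "user"`.
#' @export
load_filter_config <- function(path) {
  if (!file.exists(path)) stop("filter config not found: ", path)
  lines <- readLines(path)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  names_ <- character(0); thr <- numeric(0)
  valid <- filter_catalogue()$name
  for (i in keep) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 2L)
      stop("filter config line ", i, " is not two tab-delimited columns: ",
           lines[i], call. = FALSE)
    nm <- trimws(fields[1])
    if (!nm %in% valid)
      stop("unknown filter name '", nm, "' at line ", i,
           "; valid names are: ", paste(valid, collapse = ", "),
           call. = FALSE)
    val <- suppressWarnings(as.numeric(fields[2]))
    if (is.na(val))
      stop("non-numeric threshold '", fields[2], "' at line ", i,
           call. = FALSE)
    if (nm %in% names_)
      stop("duplicate filter name '", nm, "' at line ", i, call. = FALSE)
    names_ <- c(names_, nm); thr <- c(thr, val)
  }
  if (length(names_) == 0L)
    warning("filter config '", path,
            "' contains no filters: all variants will pass unfiltered",
            call. = FALSE)
  new_filter_config(names_, thr, "user")
}

#' Save a filter configuration file
#'
#' Writes the two-column tab-delimited format read by
#' [load_filter_config()].
#'
#' @param config A `somafilt_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_filter_config <- function(config, path) {
  lines <- c("# somafilt filter configuration (filter_name<TAB>threshold)",
             sprintf("# preset: %s", config$preset),
             sprintf("%s\t%s", config$entries$name,
                     format(config$entries$threshold, trim = TRUE,
                            scientific = FALSE)))
  writeLines(lines, path)
  invisible(path)
}

# Resolve a filter's metric value on one metrics row; strand filter derives
# the minor-strand fraction and is only applicable at >=10 alt reads.
filter_metric_value <- function(name, row) {
  cat <- filter_catalogue()
  j <- match(name, cat$name)
  if (is.na(j)) stop("unknown filter: ", name, call. = FALSE)
  if (name == "strand_minor_frac_alt_tumor") {
    ac <- row[["tumor_alt_count"]]
    if (is.na(ac) || ac < 10) return(list(value = NA_real_, applicable = FALSE))
    return(list(value = min(row[["tumor_alt_fwd"]], row[["tumor_alt_rev"]]) / ac,
                applicable = TRUE))
  }
  metric <- cat$metric[j]
  if (!metric %in% names(row))
    stop("metric column '", metric, "' absent from metrics table: ",
         "catalogue/table version mismatch", call. = FALSE)
  list(value = as.numeric(row[[metric]]), applicable = TRUE)
}

#' Evaluate one filter on one variant
#'
#' @param name Filter name from the [filter_catalogue()].
#' @param threshold Numeric threshold.
#' @param metrics_row One row of a metrics table (list or 1-row data frame).
#' @return `"pass"`, `"fail"` or `"not_applicable"`. A `min` filter fails
#'   when the metric is strictly below the threshold, a `max` filter when it
#'   is strictly above; equality passes. Missing metrics resolve via the
#'   catalogue's `na_policy`.
#' @export
evaluate_filter <- function(name, threshold, metrics_row) {
  cat <- filter_catalogue()
  j <- match(name, cat$name)
  if (is.na(j)) stop("unknown filter: ", name, call. = FALSE)
  mv <- filter_metric_value(name, metrics_row)
  if (!mv$applicable) return("not_applicable")
  if (is.na(mv$value))
    return(if (cat$na_policy[j] == "fail_on_na") "fail" else "pass")
  fail <- if (cat$direction[j] == "min") mv$value < threshold
          else mv$value > threshold
  if (fail) "fail" else "pass"
}

#' Apply a filter configuration to a metrics table
#'
#' Stage two of the pipeline: evaluates every configured filter on every
#' variant's metric panel.
#'
#' @param config A `somafilt_config`.
#' @param table A metrics table from [run_metrics_stage()] or
#'   [read_metrics_table()].
#' @return A data frame of class `somafilt_verdicts`, one row per variant in
#'   table order: the site key columns, one column per configured filter
#'   holding `"pass"`/`"fail"`/`"not_applicable"`, and `overall`, which is
#'   `"pass"` iff no filter failed.
#' @export
apply_filters <- function(config, table) {
  stopifnot(inherits(config, "somafilt_config"))
  nms <- config$entries$name
  cat <- filter_catalogue()
  out <- table[, c("contig", "pos", "ref", "alt"), drop = FALSE]
  outcome_mat <- matrix("pass", nrow = nrow(table), ncol = length(nms),
                        dimnames = list(NULL, nms))
  for (k in seq_along(nms)) {
    thr <- config$entries$threshold[k]
    j <- match(nms[k], cat$name)
    if (nms[k] == "strand_minor_frac_alt_tumor") {
      ac <- table[["tumor_alt_count"]]
      applicable <- !is.na(ac) & ac >= 10
      value <- ifelse(applicable,
                      pmin(table[["tumor_alt_fwd"]],
                           table[["tumor_alt_rev"]]) / ac, NA_real_)
    } else {
      metric <- cat$metric[j]
      if (!metric %in% names(table))
        stop("metric column '", metric, "' absent from metrics table: ",
             "catalogue/table version mismatch", call. = FALSE)
      applicable <- rep(TRUE, nrow(table))
      value <- as.numeric(table[[metric]])
    }
    fail <- if (cat$direction[j] == "min") value < thr else value > thr
    fail[is.na(fail)] <- cat$na_policy[j] == "fail_on_na"
    oc <- ifelse(fail, "fail", "pass")
    oc[!applicable] <- "not_applicable"
    outcome_mat[, k] <- oc
  }
  for (nm in nms) out[[nm]] <- outcome_mat[, nm]
  out$overall <- if (length(nms) == 0L) rep("pass", nrow(table)) else
    ifelse(apply(outcome_mat == "fail", 1, any), "fail", "pass")
  rownames(out) <- NULL
  structure(out, config = config,
            class = c("somafilt_verdicts", "data.frame"))
}

#' Summarize verdicts and plot pass/fail counts
#'
#' Writes a per-filter summary TSV (`filter_summary.tsv`) and a bar chart
#' (`filter_summary.png`) of pass/fail counts to `out_dir`. Inspecting this
#' plot is the recommended sanity check against over- or under-filtering.
#'
#' @param verdicts Verdicts from [apply_filters()].
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, a list with `summary` (data frame: `filter`, `pass`,
#'   `fail`, `not_applicable`), `total` and `overall_pass`.
#' @export
summarize_and_plot <- function(verdicts, out_dir) {
  stopifnot(inherits(verdicts, "somafilt_verdicts"), nrow(verdicts) > 0L)
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir, call. = FALSE)
  }
  config <- attr(verdicts, "config")
  nms <- config$entries$name
  summ <- data.frame(
    filter = nms,
    pass = vapply(nms, function(f) sum(verdicts[[f]] == "pass"), integer(1)),
    fail = vapply(nms, function(f) sum(verdicts[[f]] == "fail"), integer(1)),
    not_applicable = vapply(nms, function(f)
      sum(verdicts[[f]] == "not_applicable"), integer(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  total <- nrow(verdicts)
  overall_pass <- sum(verdicts$overall == "pass")

  tsv <- file.path(out_dir, "filter_summary.tsv")
  utils::write.table(summ, tsv, sep = "\t", quote = FALSE, row.names = FALSE)

  png_path <- file.path(out_dir, "filter_summary.png")
  if (length(nms) > 0L) {
    long <- data.frame(
      filter = rep(summ$filter, 2L),
      outcome = rep(c("pass", "fail"), each = nrow(summ)),
      count = c(summ$pass, summ$fail))
    p <- ggplot2::ggplot(long, ggplot2::aes(
        x = filter, y = count, fill = outcome)) +
      ggplot2::geom_col(position = "dodge") +
      ggplot2::coord_flip() +
      ggplot2::labs(x = NULL, y = "variants",
                    title = sprintf("Filter outcomes (%d variants, %d pass all)",
                                    total, overall_pass)) +
      ggplot2::theme_minimal()
    tryCatch(
      ggplot2::ggsave(png_path, p, width = 7, height = 5, dpi = 120),
      error = function(e)
        warning("could not render summary plot: ", conditionMessage(e),
                call. = FALSE))
  }
  invisible(list(summary = summ, total = total, overall_pass = overall_pass,
                 tsv = tsv, plot = png_path))
}
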