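#' Run stage one: compute the metric panel for every candidate
#'
#' Traverses the tumor and normal BAMs at every candidate site and assembles
#' the full metrics table. Variants are processed in chunks; each completed
#' chunk is persisted to `cache_dir` (as `metrics.<i>.tsv.gz`) before the
#' next begins, so an interrupted run resumes where it stopped. A
#' `fingerprint.json` manifest (candidate count, source VCF path, tool
#' version) guards against silently reusing a cache built from different
#' inputs: on mismatch the stale chunks are recomputed with a logged warning.
#'
#' @param vcf_path Candidate VCF (any caller).
#' @param tumor_bam,normal_bam Indexed, coordinate-sorted BAMs on the same
#'   reference naming as the VCF.
#' @param cache_dir Directory for chunk files (created if absent).
#' @param jobs Number of worker processes for chunk computation. Results are
#'   identical for any value of `jobs`.
#' @param chunk_size Variants per chunk (default 1000).
#' @return The metrics table (`somafilt_metrics`), rows in VCF order.
#'   Attributes `chunks_total`, `chunks_computed` and `chunks_reused` report
#'   cache behaviour for logging.
#' @export
run_metrics_stage <- function(vcf_path, tumor_bam, normal_bam, cache_dir,
                              jobs = 1L, chunk_size = 1000L) {
  stopifnot(jobs >= 1L, chunk_size >= 1L)
  candidates <- read_candidate_variants(vcf_path)
  tumor_contigs <- bam_contigs(tumor_bam)
  normal_contigs <- bam_contigs(normal_bam)
  used <- unique(candidates$contig)
  bad <- used[!(used %in% tumor_contigs & used %in% normal_contigs)]
  if (length(bad) > 0L)
    stop("contig naming mismatch before metrics computation: VCF contig(s) ",
         paste(bad, collapse = ","), " not present in both BAM headers ",
         "(tumor: ", paste(tumor_contigs, collapse = ","),
         "; normal: ", paste(normal_contigs, collapse = ","), ")",
         call. = FALSE)

  if (!dir.exists(cache_dir)) dir.create(cache_dir, recursive = TRUE)
  fp <- list(record_count = nrow(candidates),
             vcf_path = normalizePath(vcf_path),
             version = somafilt_version())
  fp_path <- file.path(cache_dir, "fingerprint.json")
  chunk_files <- list.files(cache_dir, pattern = "^metrics\\.\\d+\\.tsv\\.gz$",
                            full.names = TRUE)
  if (file.exists(fp_path)) {
    old <- tryCatch(jsonlite::read_json(fp_path, simplifyVector = TRUE),
                    error = function(e) NULL)
    if (!identical(lapply(old, as.character), lapply(fp, as.character))) {
      warning("metrics cache fingerprint mismatch in '", cache_dir,
              "': recomputing stale chunks", call. = FALSE)
      file.remove(chunk_files)
    }
  } else if (length(chunk_files) > 0L) {
    warning("metrics cache in '", cache_dir,
            "' has no fingerprint: recomputing", call. = FALSE)
    file.remove(chunk_files)
  }
  jsonlite::write_json(fp, fp_path, auto_unbox = TRUE)

  n <- nrow(candidates)
  n_chunks <- ceiling(n / chunk_size)
  chunk_idx <- function(i) {
    lo <- (i - 1L) * chunk_size + 1L
    seq(lo, min(i * chunk_size, n))
  }
  chunk_path <- function(i) file.path(cache_dir,
                                      sprintf("metrics.%d.tsv.gz", i))

  cached <- vapply(seq_len(n_chunks), function(i) file.exists(chunk_path(i)),
                   logical(1))
  todo <- which(!cached)

  compute_chunk <- function(i) {
    rows <- lapply(chunk_idx(i), function(r)
      compute_pair_metrics(tumor_bam, normal_bam,
                           candidates[r, , drop = FALSE],
                           tumor_contigs, normal_contigs))
    df <- do.call(rbind, rows)
    as_metrics_table(df[, metrics_columns()])
  }

  if (length(todo) > 0L) {
    computed <- parallel::mclapply(todo, compute_chunk,
                                   mc.cores = min(jobs, length(todo)))
    errs <- vapply(computed, inherits, logical(1), "try-error")
    if (any(errs))
      stop("metrics computation failed: ",
           conditionMessage(attr(computed[[which(errs)[1]]], "condition")),
           call. = FALSE)
    for (k in seq_along(todo))
      write_metrics_table(computed[[k]], chunk_path(todo[k]))
  }

  parts <- lapply(seq_len(n_chunks), function(i) read_metrics_table(chunk_path(i)))
  table <- as_metrics_table(do.call(rbind, parts))
  attr(table, "chunks_total") <- n_chunks
  attr(table, "chunks_computed") <- length(todo)
  attr(table, "chunks_reused") <- sum(cached)
  message(sprintf("metrics stage: %d chunks total, %d computed, %d reused from cache",
                  n_chunks, length(todo), sum(cached)))
  table
}
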