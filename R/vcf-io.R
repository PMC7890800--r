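#' Read candidate variants from a VCF
#'
#' Loads a VCF of candidate somatic variants from any caller. Only CHROM, POS,
#' REF and ALT are interpreted; every other column is carried opaquely so the
#' original record can be re-emitted verbatim. Multi-allelic records are split
#' into one candidate per ALT allele, preserving record order.
#'
#' @param path Path to a VCF file (plain or gzip/bgzip compressed).
#' @return A data frame of class `somafilt_candidates` with columns `contig`,
#'   `pos` (1-based), `ref`, `alt`, `is_snv`, `record_index` (index of the
#'   source record) and `allele_index` (which ALT of that record). Attributes
#'   `meta` (the `##` header lines) and `records` (the original data lines)
#'   support round-trip emission.
#' @details A variant is classed as an SNV iff both alleles are single bases;
#'   only SNVs receive the full metric panel downstream. Alleles must be
#'   non-empty strings over A/C/G/T/N; symbolic or breakend ALTs are rejected.
#' @export
read_candidate_variants <- function(path) {
  if (!file.exists(path)) stop("VCF not found: ", path)
  v <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) {
      bad <- first_bad_vcf_line(path)
      stop("failed to parse VCF '", path, "'",
           if (!is.null(bad)) paste0("; first offending line: ", bad),
           "\n(", conditionMessage(e), ")", call. = FALSE)
    })
  fix <- v@fix
  if (is.null(fix) || nrow(fix) == 0L) stop("empty VCF: ", path, call. = FALSE)
  gt <- v@gt

  records <- vapply(seq_len(nrow(fix)), function(i) {
    fields <- fix[i, ]
    if (!is.null(gt) && ncol(gt) > 0L) fields <- c(fields, gt[i, ])
    fields[is.na(fields)] <- "."
    paste(fields, collapse = "\t")
  }, character(1))

  out <- vector("list", nrow(fix))
  for (i in seq_len(nrow(fix))) {
    chrom <- fix[i, "CHROM"]
    pos <- suppressWarnings(as.integer(fix[i, "POS"]))
    ref <- fix[i, "REF"]
    altf <- fix[i, "ALT"]
    ok <- !is.na(chrom) && !is.na(pos) && pos >= 1L &&
      !is.na(ref) && grepl("^[ACGTNacgtn]+$", ref) &&
      !is.na(altf) && nzchar(altf)
    alts <- if (ok) strsplit(altf, ",", fixed = TRUE)[[1]] else character(0)
    if (!ok || length(alts) == 0L || !all(grepl("^[ACGTNacgtn]+$", alts)))
      stop("failed to parse VCF '", path, "'; first offending line: ",
           records[i], call. = FALSE)
    out[[i]] <- data.frame(
      contig = chrom, pos = pos,
      ref = toupper(ref), alt = toupper(alts),
      is_snv = nchar(ref) == 1L & nchar(alts) == 1L,
      record_index = i, allele_index = seq_along(alts),
      row.names = NULL, stringsAsFactors = FALSE)
  }
  cand <- do.call(rbind, out)
  rownames(cand) <- NULL
  header_line <- paste0("#", paste(c(colnames(fix),
                                     if (!is.null(gt)) colnames(gt)),
                                   collapse = "\t"))
  structure(cand,
            meta = v@meta,
            header_line = header_line,
            records = records,
            source = path,
            class = c("somafilt_candidates", "data.frame"))
}

# Locate the first data line that cannot be a VCF record (too few fields).
first_bad_vcf_line <- function(path) {
  con <- gzfile(path, open = "rt")
  on.exit(close(con))
  repeat {
    line <- tryCatch(readLines(con, n = 1L), error = function(e) character(0))
    if (length(line) == 0L) return(NULL)
    if (startsWith(line, "#")) next
    if (length(strsplit(line, "\t", fixed = TRUE)[[1]]) < 8L) return(line)
  }
}

#' Write the filtered VCF
#'
#' Emits a standard VCF whose FILTER column carries the verdicts: `PASS` when
#' every applied filter passed, otherwise a semicolon-joined list of the
#' failed filter names. All other columns are copied verbatim from the input
#' record. One `##FILTER` header line is added per applied filter (with its
#' threshold), plus provenance lines recording the tool version and preset.
#'
#' @param candidates Candidates from [read_candidate_variants()].
#' @param verdicts Verdicts from [apply_filters()], covering every candidate
#'   in the same order.
#' @param config The applied [filter configuration][default_preset].
#' @param out_path Output path (plain text VCF).
#' @param pass_only If `TRUE`, emit only records whose FILTER is `PASS`.
#'   By default filtering annotates and never deletes, so the output has
#'   exactly as many data lines as the input has records.
#' @return `out_path`, invisibly.
#' @details For a multi-allelic record the emitted FILTER is the verdict of
#'   its first ALT allele; per-allele verdicts live in the per-variant results
#'   table written by [somafilt_run()].
#' @export
write_filtered_vcf <- function(candidates, verdicts, config, out_path,
                               pass_only = FALSE) {
  stopifnot(inherits(candidates, "somafilt_candidates"))
  if (nrow(verdicts) != nrow(candidates) ||
      !all(verdicts$contig == candidates$contig &
           verdicts$pos == candidates$pos &
           verdicts$ref == candidates$ref &
           verdicts$alt == candidates$alt))
    stop("internal consistency error: verdicts do not cover the candidates",
         call. = FALSE)

  filter_names <- config$entries$name
  records <- attr(candidates, "records")
  meta <- attr(candidates, "meta")

  # FILTER string per original record: verdict of its first ALT.
  first_rows <- match(seq_along(records), candidates$record_index)
  filt <- vapply(first_rows, function(r) {
    if (is.na(r)) return(".")
    if (length(filter_names) == 0L) return("PASS")
    failed <- filter_names[vapply(filter_names, function(f)
      identical(verdicts[[f]][r], "fail"), logical(1))]
    if (length(failed) == 0L) "PASS" else paste(failed, collapse = ";")
  }, character(1))

  body <- vapply(seq_along(records), function(i) {
    fields <- strsplit(records[i], "\t", fixed = TRUE)[[1]]
    fields[7] <- filt[i]
    paste(fields, collapse = "\t")
  }, character(1))
  if (pass_only) body <- body[filt == "PASS"]

  header <- c(meta, attr(candidates, "header_line"))
  chrom_line <- grep("^#CHROM", header)
  extra <- c(
    vapply(seq_len(nrow(config$entries)), function(i) {
      nm <- config$entries$name[i]
      thr <- config$entries$threshold[i]
      desc <- filter_catalogue()$description[match(nm, filter_catalogue()$name)]
      sprintf('##FILTER=<ID=%s,Description="%s threshold=%s">', nm, desc,
              format(thr, trim = TRUE))
    }, character(1)),
    sprintf("##somafilt_version=%s", somafilt_version()),
    sprintf("##somafilt_preset=%s", config$preset))
  if (length(chrom_line) == 1L) {
    header <- append(header, extra, after = chrom_line - 1L)
  } else {
    header <- c(header, extra)
  }
  writeLines(c(header, body), out_path)
  invisible(out_path)
}

#' Read a truth set of somatic SNVs
#'
#' Accepts either a VCF (only `PASS` / unfiltered records are kept) or a
#' 4-column tab-delimited file (`contig`, `pos`, `ref`, `alt`, `#` comments
#' allowed, header optional).
#'
#' @param path Path to a truth VCF or TSV.
#' @return A data frame with columns `contig`, `pos`, `ref`, `alt`.
#' @export
read_truth <- function(path) {
  if (!file.exists(path)) stop("truth file not found: ", path)
  if (is_vcf_file(path)) {
    cand <- read_candidate_variants(path)
    recs <- attr(cand, "records")
    filt <- vapply(strsplit(recs, "\t", fixed = TRUE), `[`, character(1), 7)
    keep <- filt[cand$record_index] %in% c("PASS", ".")
    return(as.data.frame(cand[keep, c("contig", "pos", "ref", "alt")],
                         row.names = NULL))
  }
  tab <- utils::read.delim(path, header = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 4L) stop("truth TSV must have 4 columns: contig, pos, ref, alt")
  tab <- tab[, 1:4]
  names(tab) <- c("contig", "pos", "ref", "alt")
  if (is.character(tab$pos)) {  # header row present
    tab <- tab[suppressWarnings(!is.na(as.integer(tab$pos))), , drop = FALSE]
  }
  tab$contig <- as.character(tab$contig)
  tab$pos <- as.integer(tab$pos)
  tab$ref <- toupper(as.character(tab$ref))
  tab$alt <- toupper(as.character(tab$alt))
  rownames(tab) <- NULL
  tab
}

is_vcf_file <- function(path) {
  if (grepl("\\.vcf(\\.gz|\\.bgz)?$", path)) return(TRUE)
  con <- gzfile(path, open = "rt")
  on.exit(close(con))
  first <- tryCatch(readLines(con, n = 1L), error = function(e) "")
  length(first) == 1L && startsWith(first, "##fileformat=VCF")
}
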