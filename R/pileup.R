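# CIGAR parsing: returns data.frame of op lengths and codes.
parse_cigar <- function(cigar) {
  m <- gregexpr("\\d+[MIDNSHP=X]", cigar)[[1]]
  toks <- regmatches(cigar, list(m))[[1]]
  data.frame(len = as.integer(sub("[A-Z=]$", "", toks)),
             op = sub("^\\d+", "", toks), stringsAsFactors = FALSE)
}

# Walk one alignment's CIGAR and locate a 1-based reference position.
# Returns list(kind = "base"/"del"/"refskip"/"outside", query_pos (0-based),
# near_indel) where near_indel is TRUE if any I/D op's reference footprint
# lies within `window` bp of the site.
locate_site_in_read <- function(read_pos, cigar, site_pos, window = 5L) {
  # fast path for ungapped alignments
  if (grepl("^\\d+M$", cigar)) {
    len <- as.integer(sub("M", "", cigar, fixed = TRUE))
    if (site_pos >= read_pos && site_pos <= read_pos + len - 1L)
      return(list(kind = "base", query_pos = site_pos - read_pos,
                  near_indel = FALSE))
    return(list(kind = "outside", query_pos = NA_integer_,
                near_indel = FALSE))
  }
  ops <- parse_cigar(cigar)
  qpos <- 0L
  rpos <- read_pos
  kind <- "outside"
  query_pos <- NA_integer_
  near <- FALSE
  for (i in seq_len(nrow(ops))) {
    op <- ops$op[i]; len <- ops$len[i]
    if (op %in% c("M", "=", "X")) {
      if (site_pos >= rpos && site_pos <= rpos + len - 1L && kind == "outside") {
        kind <- "base"
        query_pos <- qpos + (site_pos - rpos)
      }
      qpos <- qpos + len; rpos <- rpos + len
    } else if (op == "I") {
      # insertion sits between rpos-1 and rpos on the reference
      if (min(abs(site_pos - (rpos - 1L)), abs(site_pos - rpos)) <= window)
        near <- TRUE
      qpos <- qpos + len
    } else if (op == "D") {
      if (site_pos >= rpos - window && site_pos <= rpos + len - 1L + window)
        near <- TRUE
      if (site_pos >= rpos && site_pos <= rpos + len - 1L && kind == "outside")
        kind <- "del"
      rpos <- rpos + len
    } else if (op == "N") {
      if (site_pos >= rpos && site_pos <= rpos + len - 1L && kind == "outside")
        kind <- "refskip"
      rpos <- rpos + len
    } else if (op == "S") {
      qpos <- qpos + len
    }
    # H and P consume neither query nor reference
  }
  list(kind = kind, query_pos = query_pos, near_indel = near)
}

# Header targets of a BAM, memoised per call site by the caller if needed.
bam_contigs <- function(bam_path) {
  names(Rsamtools::scanBamHeader(bam_path)[[1]]$targets)
}

#' Collect per-read observations at a candidate site
#'
#' Queries an indexed, coordinate-sorted BAM for all reads overlapping the
#' site and extracts one observation per included read. Unmapped, secondary,
#' supplementary, QC-fail and duplicate-flagged reads are excluded; improper
#' pairs and mapping-quality-zero reads are included (they feed the
#' `improper_pair_frac_alt` and `mq0_frac` metrics). Reads whose alignment
#' carries a deletion or reference skip across the site yield a
#' `DEL`/`REFSKIP`-marked observation that still counts toward depth.
#'
#' @param bam_path Path to an indexed BAM (a matching `.bai` must exist).
#' @param site A list or 1-row data frame with `contig`, `pos`, `ref`, `alt`.
#' @param contigs Optional precomputed header contig names (avoids re-reading
#'   the header in tight loops).
#' @return A data frame with one row per included read: `base` (the read's
#'   base at the site, or `DEL`/`REFSKIP`), `base_quality` (`NA` when the
#'   read has no quality string), `mapping_quality`, `strand`
#'   (`"+"`/`"-"`), `query_pos` (0-based offset within the query),
#'   `read_length`, `has_softclip`, `nm` (NM tag, `NA` when absent),
#'   `properly_paired`, `near_indel` (an I/D op within 5 reference bp of the
#'   site), and allele-match flags `alt_match`/`ref_match` (exact allele
#'   string match at the site, supporting non-SNV counting).
#' @export
collect_read_observations <- function(bam_path, site, contigs = NULL) {
  contig <- as.character(site$contig)
  pos <- as.integer(site$pos)
  if (is.null(contigs)) contigs <- bam_contigs(bam_path)
  if (!contig %in% contigs)
    stop("contig '", contig, "' absent from BAM header of '", bam_path,
         "' (header contigs: ", paste(contigs, collapse = ", "), ")",
         call. = FALSE)

  which <- IRanges::IRangesList(IRanges::IRanges(pos, pos))
  names(which) <- contig
  param <- Rsamtools::ScanBamParam(
    which = which,
    what = c("flag", "pos", "mapq", "cigar", "seq", "qual", "strand"),
    tag = "NM",
    flag = Rsamtools::scanBamFlag(
      isUnmappedQuery = FALSE, isSecondaryAlignment = FALSE,
      isSupplementaryAlignment = FALSE, isDuplicate = FALSE,
      isNotPassingQualityControls = FALSE))
  res <- Rsamtools::scanBam(bam_path, param = param)[[1]]
  n <- length(res$pos)
  empty <- data.frame(
    base = character(0), base_quality = numeric(0),
    mapping_quality = numeric(0), strand = character(0),
    query_pos = integer(0), read_length = integer(0),
    has_softclip = logical(0), nm = numeric(0),
    properly_paired = logical(0), near_indel = logical(0),
    alt_match = logical(0), ref_match = logical(0),
    stringsAsFactors = FALSE)
  if (n == 0L) return(empty)

  seqs <- as.character(res$seq)
  quals <- as.character(res$qual)
  nm_tag <- res$tag$NM
  if (is.null(nm_tag)) nm_tag <- rep(NA_integer_, n)
  ref_allele <- toupper(as.character(site$ref))
  alt_allele <- toupper(as.character(site$alt))

  base <- character(n); bq <- rep(NA_real_, n)
  qp <- rep(NA_integer_, n); near <- logical(n)
  alt_match <- logical(n); ref_match <- logical(n)
  keep <- logical(n)
  rl <- nchar(seqs)
  has_qual <- nchar(quals) == rl
  for (i in seq_len(n)) {
    loc <- locate_site_in_read(res$pos[i], res$cigar[i], pos)
    if (loc$kind == "outside") next
    keep[i] <- TRUE
    near[i] <- loc$near_indel
    if (loc$kind == "base") {
      q <- loc$query_pos
      qp[i] <- q
      base[i] <- toupper(substr(seqs[i], q + 1L, q + 1L))
      if (has_qual[i])
        bq[i] <- utf8ToInt(substr(quals[i], q + 1L, q + 1L)) - 33L
      sub_alt <- toupper(substr(seqs[i], q + 1L, q + nchar(alt_allele)))
      alt_match[i] <- identical(sub_alt, alt_allele)
      if (!alt_match[i]) {
        sub_ref <- toupper(substr(seqs[i], q + 1L, q + nchar(ref_allele)))
        ref_match[i] <- identical(sub_ref, ref_allele)
      }
    } else {
      base[i] <- if (loc$kind == "del") "DEL" else "REFSKIP"
    }
  }
  if (!any(keep)) return(empty)
  out <- data.frame(
    base = base[keep], base_quality = bq[keep],
    mapping_quality = as.numeric(res$mapq[keep]),
    strand = as.character(res$strand[keep]),
    query_pos = qp[keep], read_length = rl[keep],
    has_softclip = grepl("S", res$cigar[keep], fixed = TRUE),
    nm = as.numeric(nm_tag[keep]),
    properly_paired = bitwAnd(res$flag[keep], 2L) > 0L,
    near_indel = near[keep],
    alt_match = alt_match[keep], ref_match = ref_match[keep],
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Summarize read observations into the per-sample metric panel
#'
#' Computes all per-sample site metrics from the observation list of one
#' sample at one candidate site. Allele classing: a read whose query matches
#' the ALT allele exactly is `alt`; otherwise a REF match is `ref`; anything
#' else (including deletions, reference skips and third alleles) is `other`.
#'
#' Medians use the midpoint convention for even counts; the MAD is the raw
#' median absolute deviation with no consistency scaling. Alt-conditioned
#' statistics are `NA` exactly when there are no alt reads; `vaf` is `NA`
#' exactly when depth is zero. Reads without a quality string are excluded
#' from base-quality medians only.
#'
#' For non-SNV candidates only depth, the allele counts and VAF are
#' computed (alt defined by exact allele match at the position); all
#' read-geometry metrics are `NA`.
#'
#' @param observations Data frame from [collect_read_observations()].
#' @param site A list or 1-row data frame with `contig`, `pos`, `ref`, `alt`.
#' @return Named list with the fields of the per-sample panel (see
#'   [metrics_columns()]).
#' @export
summarize_site <- function(observations, site) {
  obs <- observations
  is_snv <- nchar(as.character(site$ref)) == 1L &&
    nchar(as.character(site$alt)) == 1L
  depth <- nrow(obs)
  klass <- ifelse(obs$alt_match, "alt", ifelse(obs$ref_match, "ref", "other"))
  alt <- obs[klass == "alt", , drop = FALSE]
  ref <- obs[klass == "ref", , drop = FALSE]
  alt_count <- nrow(alt)
  ref_count <- nrow(ref)
  other_count <- depth - alt_count - ref_count
  vaf <- if (depth == 0L) NA_real_ else alt_count / depth

  m <- list(depth = depth, ref_count = ref_count, alt_count = alt_count,
            other_count = other_count, vaf = vaf)
  na_panel <- setNames(as.list(rep(NA_real_, 15L)),
                       setdiff(sample_metric_names(), names(m)))
  if (!is_snv) return(c(m, na_panel))

  m$median_bq_alt <- if (alt_count == 0L) NA_real_ else
    median_or_na(alt$base_quality)
  m$median_bq_ref <- if (ref_count == 0L) NA_real_ else
    median_or_na(ref$base_quality)
  m$median_mq_alt <- if (alt_count == 0L) NA_real_ else
    median_or_na(alt$mapping_quality)
  m$median_mq_all <- if (depth == 0L) NA_real_ else
    median_or_na(obs$mapping_quality)
  m$alt_fwd <- sum(alt$strand == "+")
  m$alt_rev <- sum(alt$strand == "-")
  m$ref_fwd <- sum(ref$strand == "+")
  m$ref_rev <- sum(ref$strand == "-")
  m$median_dist_readend_alt <- if (alt_count == 0L) NA_real_ else
    median_or_na(pmin(alt$query_pos, alt$read_length - 1L - alt$query_pos))
  m$mad_pos_alt <- if (alt_count == 0L) NA_real_ else
    mad_unscaled(alt$query_pos)
  m$softclip_frac_alt <- if (alt_count == 0L) NA_real_ else
    mean(alt$has_softclip)
  m$mean_excess_nm_alt <- if (alt_count == 0L) NA_real_ else {
    nm <- alt$nm[!is.na(alt$nm)]
    if (length(nm) == 0L) NA_real_ else mean(pmax(nm - 1, 0))
  }
  m$mq0_frac <- if (depth == 0L) NA_real_ else
    mean(obs$mapping_quality == 0)
  m$near_indel_frac <- if (depth == 0L) NA_real_ else mean(obs$near_indel)
  m$improper_pair_frac_alt <- if (alt_count == 0L) NA_real_ else
    mean(!alt$properly_paired)
  m[sample_metric_names()]
}

#' Compute the paired metric panel at one site
#'
#' Runs [collect_read_observations()] and [summarize_site()] on the tumor
#' and the normal BAM at the same candidate site.
#'
#' @param tumor_bam,normal_bam Paths to indexed BAMs on the same reference.
#' @param site A list or 1-row data frame with `contig`, `pos`, `ref`, `alt`.
#' @param tumor_contigs,normal_contigs Optional precomputed header contigs.
#' @return A 1-row data frame: site key plus `tumor_*` and `normal_*` panels.
#' @export
compute_pair_metrics <- function(tumor_bam, normal_bam, site,
                                 tumor_contigs = NULL,
                                 normal_contigs = NULL) {
  if (is.null(tumor_contigs)) tumor_contigs <- bam_contigs(tumor_bam)
  if (is.null(normal_contigs)) normal_contigs <- bam_contigs(normal_bam)
  contig <- as.character(site$contig)
  in_t <- contig %in% tumor_contigs
  in_n <- contig %in% normal_contigs
  if (!in_t || !in_n)
    stop("contig naming mismatch: '", contig, "' is ",
         if (in_t) "present" else "absent", " in the tumor BAM and ",
         if (in_n) "present" else "absent", " in the normal BAM (tumor: ",
         paste(utils::head(tumor_contigs, 5), collapse = ","), "; normal: ",
         paste(utils::head(normal_contigs, 5), collapse = ","), ")",
         call. = FALSE)
  t_obs <- collect_read_observations(tumor_bam, site, tumor_contigs)
  n_obs <- collect_read_observations(normal_bam, site, normal_contigs)
  t_m <- summarize_site(t_obs, site)
  n_m <- summarize_site(n_obs, site)
  row <- c(list(contig = contig, pos = as.integer(site$pos),
                ref = toupper(as.character(site$ref)),
                alt = toupper(as.character(site$alt))),
           setNames(t_m, paste0("tumor_", names(t_m))),
           setNames(n_m, paste0("normal_", names(n_m))))
  as.data.frame(row, stringsAsFactors = FALSE)
}
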