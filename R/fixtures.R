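# Artifact classes and the default-preset filter each is built to trip.
artifact_classes <- function() {
  c(low_vaf = "min_vaf_tumor",
    germline_leak = "max_vaf_normal",
    low_bq = "min_median_bq_alt_tumor",
    low_mq = "min_median_mq_alt_tumor",
    strand_artifact = "strand_minor_frac_alt_tumor",
    readend_artifact = "min_median_dist_readend_alt_tumor",
    fixed_pos_artifact = "min_mad_pos_alt_tumor",
    softclip_artifact = "max_softclip_frac_alt_tumor",
    noisy_read_artifact = "max_excess_nm_alt_tumor",
    mq0_artifact = "max_mq0_frac_tumor",
    near_indel_artifact = "max_near_indel_frac_tumor",
    improper_pair_artifact = "max_improper_pair_frac_alt_tumor")
}

#' Generate a deterministic random reference sequence
#'
#' Uniform-random A/C/G/T sequence on a single contig named `synth1`,
#' written as a faidx-compatible FASTA (and indexed).
#'
#' @param length Sequence length in bp (at least 1000).
#' @param seed Integer seed; the same seed always yields the same sequence.
#' @param path Optional FASTA output path; a temp file when `NULL`.
#' @return List with `seq` (character string) and `path` (FASTA file).
#' @export
make_reference <- function(length, seed, path = NULL) {
  if (length < 1000) stop("reference length must be at least 1000 bp",
                          call. = FALSE)
  seq <- with_seed(seed, paste(sample(c("A", "C", "G", "T"), length,
                                      replace = TRUE), collapse = ""))
  if (is.null(path)) path <- tempfile(fileext = ".fa")
  dss <- Biostrings::DNAStringSet(seq)
  names(dss) <- "synth1"
  Biostrings::writeXStringSet(dss, path, width = 70L)
  Rsamtools::indexFa(path)
  list(seq = seq, path = path)
}

# Build one aligned read over refseq: walk the CIGAR, copying reference for
# M ops (substituting alt_base at site_pos when alt), random bases for S/I.
# Returns a 1-row data.frame in SAM field terms.
build_read <- function(refseq, start, cigar, strand, mapq, bq,
                       site_pos = NA, alt_base = NULL, proper = TRUE,
                       dup = FALSE, secondary = FALSE, nm = NA) {
  ops <- parse_cigar(cigar)
  seq_parts <- character(0)
  rpos <- start
  indel_len <- 0L
  for (i in seq_len(nrow(ops))) {
    op <- ops$op[i]; len <- ops$len[i]
    if (op %in% c("M", "=", "X")) {
      frag <- substr(refseq, rpos, rpos + len - 1L)
      if (!is.null(alt_base) && !is.na(site_pos) &&
          site_pos >= rpos && site_pos <= rpos + len - 1L) {
        k <- site_pos - rpos + 1L
        substr(frag, k, k) <- alt_base
      }
      seq_parts <- c(seq_parts, frag)
      rpos <- rpos + len
    } else if (op %in% c("S", "I")) {
      seq_parts <- c(seq_parts, paste(sample(c("A", "C", "G", "T"), len,
                                             replace = TRUE), collapse = ""))
      if (op == "I") indel_len <- indel_len + len
    } else if (op %in% c("D", "N")) {
      if (op == "D") indel_len <- indel_len + len
      rpos <- rpos + len
    }
  }
  seq <- paste(seq_parts, collapse = "")
  if (is.na(nm)) nm <- (!is.null(alt_base)) + indel_len
  flag <- 1L + 64L +
    (if (proper) 2L else 0L) +
    (if (strand == "-") 16L else 0L) +
    (if (dup) 1024L else 0L) +
    (if (secondary) 256L else 0L)
  data.frame(qname = NA_character_, flag = flag, pos = start, mapq = mapq,
             cigar = cigar, seq = seq,
             qual = strrep(intToUtf8(bq + 33L), nchar(seq)),
             nm = as.integer(nm), stringsAsFactors = FALSE)
}

# n plain 100M reads with the site at uniformly chosen offsets.
plain_reads <- function(refseq, site_pos, n, offsets = NULL, strand = NULL,
                        mapq = 60, bq = 35, alt_base = NULL, proper = TRUE,
                        read_len = 100L) {
  if (n == 0L) return(NULL)
  if (is.null(offsets))
    offsets <- sample(10:(read_len - 11L), n, replace = TRUE)
  if (is.null(strand)) strand <- rep(c("+", "-"), length.out = n)
  mapq <- rep(mapq, length.out = n)
  bq <- rep(bq, length.out = n)
  proper <- rep(proper, length.out = n)
  do.call(rbind, lapply(seq_len(n), function(i)
    build_read(refseq, site_pos - offsets[i],
               paste0(read_len, "M"), strand[i], mapq[i],
               if (length(bq) > 1) bq[i] else bq,
               site_pos = site_pos, alt_base = alt_base, proper = proper[i])))
}

#' Plant one candidate site's read sets
#'
#' Draws the tumor and normal reads for a single locus of the requested
#' class. `true_somatic` sites emulate a clean somatic SNV: tumor alt reads
#' binomially sampled at the target VAF with balanced strands, base quality
#' ~ N(35, 3) clipped to \[2, 41\], mapping quality 60 and alt positions
#' uniform within the read; the normal is pure reference. Each artifact
#' class instead violates exactly its targeted metric threshold by a
#' comfortable margin (all alt reads on one strand, all at one query
#' position, within 5 bp of a read end, soft-clipped, high-NM, and so on);
#' `germline_leak` additionally plants the alt in the normal at VAF 0.5.
#'
#' @param klass One of `true_somatic` or the artifact classes listed by
#'   `names(somafilt:::artifact_classes())`.
#' @param refseq Reference sequence string (from [make_reference()]).
#' @param pos 1-based site position, at least 200 bp from either end.
#' @param seed Integer seed for this locus.
#' @param depth,normal_depth Target read depths (default 80).
#' @param vaf Target tumor VAF for `true_somatic` (default 0.4).
#' @return List with `site` (contig/pos/ref/alt), `tumor` and `normal` read
#'   tables, `klass`, `expected_failing_filter` (`NA` for `true_somatic`)
#'   and `target_vaf`.
#' @export
plant_site <- function(klass, refseq, pos, seed, depth = 80L,
                       normal_depth = 80L, vaf = 0.4) {
  valid <- c("true_somatic", names(artifact_classes()))
  if (!klass %in% valid)
    stop("unknown site class '", klass, "'; valid classes: ",
         paste(valid, collapse = ", "), call. = FALSE)
  if (pos < 200 || pos > nchar(refseq) - 200)
    stop("parameter 'pos' (", pos,
         ") must lie at least 200 bp inside the reference", call. = FALSE)
  if (depth < 1 || normal_depth < 1)
    stop("parameter 'depth' must be at least 1", call. = FALSE)
  if (vaf <= 0 || vaf > 1)
    stop("parameter 'vaf' must be in (0, 1]", call. = FALSE)

  with_seed(seed, {
    ref_base <- substr(refseq, pos, pos)
    alt_base <- sample(setdiff(c("A", "C", "G", "T"), ref_base), 1L)
    clip_bq <- function(n) pmin(pmax(round(rnorm(n, 35, 3)), 2), 41)

    alt_n <- switch(klass,
      true_somatic = rbinom(1L, depth, vaf),
      low_vaf = max(1L, round(0.025 * depth)),
      strand_artifact = 12L,
      round(0.4 * depth))
    ref_n <- depth - alt_n

    t_alt <- NULL
    t_ref <- plain_reads(refseq, pos, ref_n)
    if (klass == "true_somatic" || klass == "low_vaf" ||
        klass == "germline_leak") {
      t_alt <- plain_reads(refseq, pos, alt_n, bq = clip_bq(alt_n),
                           alt_base = alt_base)
    } else if (klass == "low_bq") {
      t_alt <- plain_reads(refseq, pos, alt_n, bq = 15, alt_base = alt_base)
    } else if (klass == "low_mq") {
      t_alt <- plain_reads(refseq, pos, alt_n, mapq = 20, alt_base = alt_base)
    } else if (klass == "strand_artifact") {
      t_alt <- plain_reads(refseq, pos, alt_n, strand = rep("+", alt_n),
                           bq = clip_bq(alt_n), alt_base = alt_base)
    } else if (klass == "readend_artifact") {
      t_alt <- plain_reads(refseq, pos, alt_n,
                           offsets = sample(0:4, alt_n, replace = TRUE),
                           bq = clip_bq(alt_n), alt_base = alt_base)
    } else if (klass == "fixed_pos_artifact") {
      t_alt <- plain_reads(refseq, pos, alt_n, offsets = rep(30L, alt_n),
                           bq = clip_bq(alt_n), alt_base = alt_base)
    } else if (klass == "softclip_artifact") {
      t_alt <- do.call(rbind, lapply(seq_len(alt_n), function(i) {
        o <- sample(10:69, 1L)  # offset within the 80M block
        build_read(refseq, pos - o, "20S80M",
                   if (i %% 2 == 0) "+" else "-", 60, clip_bq(1L),
                   site_pos = pos, alt_base = alt_base)
      }))
    } else if (klass == "noisy_read_artifact") {
      t_alt <- plain_reads(refseq, pos, alt_n, bq = clip_bq(alt_n),
                           alt_base = alt_base)
      t_alt$nm <- 6L
    } else if (klass == "mq0_artifact") {
      t_alt <- plain_reads(refseq, pos, alt_n, bq = clip_bq(alt_n),
                           alt_base = alt_base)
      n_mq0 <- round(0.4 * ref_n)
      t_ref <- plain_reads(refseq, pos, ref_n,
                           mapq = c(rep(0, n_mq0), rep(60, ref_n - n_mq0)))
    } else if (klass == "near_indel_artifact") {
      n_ind_alt <- ceiling(0.6 * alt_n)
      n_ind_ref <- ceiling(0.6 * ref_n)
      indel_read <- function(with_alt) {
        o <- sample(40:50, 1L)  # deletion 3 bp downstream of the site
        build_read(refseq, pos - o, paste0(o + 3, "M3D", 97 - o, "M"),
                   sample(c("+", "-"), 1L), 60,
                   if (with_alt) clip_bq(1L) else 35,
                   site_pos = pos,
                   alt_base = if (with_alt) alt_base else NULL)
      }
      t_alt <- rbind(
        do.call(rbind, lapply(seq_len(n_ind_alt), function(i) indel_read(TRUE))),
        plain_reads(refseq, pos, alt_n - n_ind_alt, bq = clip_bq(alt_n - n_ind_alt),
                    alt_base = alt_base))
      t_ref <- rbind(
        do.call(rbind, lapply(seq_len(n_ind_ref), function(i) indel_read(FALSE))),
        plain_reads(refseq, pos, ref_n - n_ind_ref))
    } else if (klass == "improper_pair_artifact") {
      t_alt <- plain_reads(refseq, pos, alt_n, bq = clip_bq(alt_n),
                           alt_base = alt_base, proper = FALSE)
    }
    tumor <- rbind(t_ref, t_alt)

    if (klass == "germline_leak") {
      n_alt_n <- round(0.5 * normal_depth)
      normal <- rbind(
        plain_reads(refseq, pos, normal_depth - n_alt_n),
        plain_reads(refseq, pos, n_alt_n, bq = clip_bq(n_alt_n),
                    alt_base = alt_base))
    } else {
      normal <- plain_reads(refseq, pos, normal_depth)
    }

    expected <- if (klass == "true_somatic") NA_character_ else
      unname(artifact_classes()[klass])
    list(site = list(contig = "synth1", pos = pos, ref = ref_base,
                     alt = alt_base),
         tumor = tumor, normal = normal, klass = klass,
         expected_failing_filter = expected,
         target_vaf = if (klass == "true_somatic") vaf else NA_real_)
  })
}

#' Write a read table to a sorted, indexed BAM
#'
#' Serializes a fixture read table (as produced by [plant_site()], or built
#' by hand for tests) through SAM text to a coordinate-sorted, indexed BAM
#' on the single contig `synth1`.
#'
#' @param reads Data frame with columns `qname` (NA for auto-naming),
#'   `flag`, `pos`, `mapq`, `cigar`, `seq`, `qual`, `nm` (NA to omit the
#'   NM tag).
#' @param ref_length Length of the `synth1` contig.
#' @param out_prefix Output path without the `.bam` extension.
#' @return Path to the BAM file (its `.bai` index sits alongside).
#' @export
write_synthetic_bam <- function(reads, ref_length, out_prefix) {
  if (is.null(reads$qname) || anyNA(reads$qname))
    reads$qname <- sprintf("read%06d", seq_len(nrow(reads)))
  header <- c("@HD\tVN:1.6\tSO:unknown",
              sprintf("@SQ\tSN:synth1\tLN:%d", as.integer(ref_length)))
  lines <- vapply(seq_len(nrow(reads)), function(i) {
    base <- paste(reads$qname[i], reads$flag[i], "synth1", reads$pos[i],
                  reads$mapq[i], reads$cigar[i], "*", 0L, 0L,
                  reads$seq[i], reads$qual[i], sep = "\t")
    if (!is.na(reads$nm[i])) base <- paste0(base, "\tNM:i:", reads$nm[i])
    base
  }, character(1))
  sam <- paste0(out_prefix, ".sam")
  writeLines(c(header, lines), sam)
  bam <- Rsamtools::asBam(sam, out_prefix, overwrite = TRUE,
                          indexDestination = TRUE)
  unlink(sam)
  bam
}

#' Generate a paired tumor/normal fixture
#'
#' Emits a complete, seeded, download-free test data set: a random
#' reference, sorted and indexed tumor and normal BAMs, a candidate VCF
#' containing every planted site, a truth TSV of the true somatic sites and
#' a JSON manifest. Fully deterministic for a given seed.
#'
#' Scenarios:
#' \describe{
#'   \item{`artifact_suite`}{24 true somatic sites (VAF cycling 0.2/0.3/0.4)
#'     plus 3 sites of each of the 12 artifact classes.}
#'   \item{`vaf_sweep`}{true somatic sites at VAFs 0.02, 0.05, 0.10, 0.20
#'     and 0.40, 12 replicates each.}
#'   \item{`clean`}{20 true somatic sites, no artifacts.}
#' }
#'
#' @param scenario `"artifact_suite"`, `"vaf_sweep"` or `"clean"`.
#' @param seed Integer master seed; per-locus generators are derived from it
#'   so loci are reproducible independent of generation order.
#' @param out_dir Output directory (created if absent).
#' @return The manifest: a list with `seed`, `scenario`, `reference`
#'   (path/length/contig), `sites` (data frame with class, site key,
#'   expected failing filter, target VAF, depth) and `files` (paths of the
#'   emitted BAMs, VCF, truth TSV and manifest JSON).
#' @export
generate_pair <- function(scenario = c("artifact_suite", "vaf_sweep", "clean"),
                          seed, out_dir) {
  scenario <- match.arg(scenario)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  plan <- switch(scenario,
    artifact_suite = rbind(
      data.frame(klass = "true_somatic",
                 vaf = rep(c(0.2, 0.3, 0.4), length.out = 24),
                 stringsAsFactors = FALSE),
      data.frame(klass = rep(names(artifact_classes()), each = 3),
                 vaf = NA_real_, stringsAsFactors = FALSE)),
    vaf_sweep = data.frame(
      klass = "true_somatic",
      vaf = rep(c(0.02, 0.05, 0.10, 0.20, 0.40), each = 12),
      stringsAsFactors = FALSE),
    clean = data.frame(klass = "true_somatic", vaf = rep(0.4, 20),
                       stringsAsFactors = FALSE))
  n_sites <- nrow(plan)
  ref_len <- 2000L + n_sites * 1500L
  ref <- make_reference(ref_len, seed, file.path(out_dir, "reference.fa"))

  tumor_list <- vector("list", n_sites)
  normal_list <- vector("list", n_sites)
  sites <- vector("list", n_sites)
  for (i in seq_len(n_sites)) {
    pos <- 1000L + (i - 1L) * 1500L
    p <- plant_site(plan$klass[i], ref$seq, pos, locus_seed(seed, i),
                    vaf = if (is.na(plan$vaf[i])) 0.4 else plan$vaf[i])
    p$tumor$qname <- sprintf("L%04d_t%04d", i, seq_len(nrow(p$tumor)))
    p$normal$qname <- sprintf("L%04d_n%04d", i, seq_len(nrow(p$normal)))
    tumor_list[[i]] <- p$tumor
    normal_list[[i]] <- p$normal
    sites[[i]] <- data.frame(
      klass = p$klass, contig = p$site$contig, pos = p$site$pos,
      ref = p$site$ref, alt = p$site$alt,
      expected_failing_filter = p$expected_failing_filter,
      target_vaf = p$target_vaf, depth = nrow(p$tumor),
      stringsAsFactors = FALSE)
  }
  sites <- do.call(rbind, sites)

  tumor_bam <- write_synthetic_bam(do.call(rbind, tumor_list), ref_len,
                                   file.path(out_dir, "tumor"))
  normal_bam <- write_synthetic_bam(do.call(rbind, normal_list), ref_len,
                                    file.path(out_dir, "normal"))

  vcf_path <- file.path(out_dir, "candidates.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=synth1,length=%d>", ref_len),
    "##source=somafilt synthetic fixture generator",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO"),
          collapse = "\t"),
    sprintf("synth1\t%d\t.\t%s\t%s\t.\t.\t.", sites$pos, sites$ref,
            sites$alt)), vcf_path)

  truth_path <- file.path(out_dir, "truth.tsv")
  tr <- sites[sites$klass == "true_somatic", c("contig", "pos", "ref", "alt")]
  writeLines(c("# true somatic sites (contig, pos, ref, alt)",
               sprintf("%s\t%d\t%s\t%s", tr$contig, tr$pos, tr$ref, tr$alt)),
             truth_path)

  manifest_path <- file.path(out_dir, "manifest.json")
  manifest <- list(
    seed = seed, scenario = scenario,
    reference = list(path = ref$path, length = ref_len, contig = "synth1"),
    sites = sites,
    files = list(tumor_bam = tumor_bam, normal_bam = normal_bam,
                 vcf = vcf_path, truth = truth_path,
                 manifest = manifest_path))
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  structure(manifest, class = "somafilt_manifest")
}
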