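# Shared fixtures, generated once per test run and cached in tempdir().
.fixture_cache <- new.env(parent = emptyenv())

fixture_seed <- function(scenario) {
  switch(scenario, artifact_suite = 101L, vaf_sweep = 202L, clean = 303L)
}

shared_fixture <- function(scenario) {
  key <- scenario
  if (!exists(key, envir = .fixture_cache)) {
    dir <- file.path(tempdir(), paste0("somafilt_fix_", scenario))
    assign(key, generate_pair(scenario, fixture_seed(scenario), dir),
           envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Metrics table for a shared fixture, computed once.
shared_metrics <- function(scenario) {
  key <- paste0("metrics_", scenario)
  if (!exists(key, envir = .fixture_cache)) {
    m <- shared_fixture(scenario)
    tab <- suppressMessages(run_metrics_stage(
      m$files$vcf, m$files$tumor_bam, m$files$normal_bam,
      cache_dir = file.path(dirname(m$files$vcf), "metrics_cache")))
    assign(key, tab, envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

manifest_sites <- function(manifest) {
  as.data.frame(manifest$sites, stringsAsFactors = FALSE)
}

# Write a small VCF from header + data lines; returns the path.
write_tiny_vcf <- function(data_lines, path = tempfile(fileext = ".vcf"),
                           contig = "chr1") {
  writeLines(c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=1000000>", contig),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO"),
          collapse = "\t"),
    data_lines), path)
  path
}

# A random pileup observation table in the shape collect_read_observations()
# returns, for an SNV site with ref A / alt T. Includes DEL rows, missing
# base qualities, absent NM tags, MAPQ-0 reads and improper pairs.
random_observations <- function(n) {
  base <- sample(c("T", "A", "C", "G", "DEL"), n, replace = TRUE,
                 prob = c(0.35, 0.45, 0.05, 0.05, 0.10))
  read_length <- rep(100L, n)
  query_pos <- ifelse(base == "DEL", NA_integer_,
                      sample(0:99L, n, replace = TRUE))
  data.frame(
    base = base,
    base_quality = ifelse(base == "DEL" | runif(n) < 0.05, NA_real_,
                          sample(2:41, n, replace = TRUE)),
    mapping_quality = sample(c(0, 20, 40, 60), n, replace = TRUE,
                             prob = c(0.1, 0.1, 0.2, 0.6)),
    strand = sample(c("+", "-"), n, replace = TRUE),
    query_pos = query_pos,
    read_length = read_length,
    has_softclip = runif(n) < 0.2,
    nm = ifelse(runif(n) < 0.1, NA_real_, sample(0:8, n, replace = TRUE)),
    properly_paired = runif(n) < 0.9,
    near_indel = runif(n) < 0.15,
    alt_match = base == "T",
    ref_match = base == "A",
    stringsAsFactors = FALSE)
}

snv_site <- function(pos = 100L, ref = "A", alt = "T", contig = "chr1") {
  list(contig = contig, pos = pos, ref = ref, alt = alt)
}

# Metrics table as a bare data frame, cache-bookkeeping attributes dropped.
tab_df <- function(x) {
  x <- as.data.frame(x)
  for (a in c("chunks_total", "chunks_computed", "chunks_reused"))
    attr(x, a) <- NULL
  x
}
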