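test_that("read inclusion honours SAM flags and empty regions", {
  ref <- make_reference(2000, 900)
  # 10 reads over the site: 2 duplicates and 1 secondary must be excluded
  set.seed(1)
  reads <- do.call(rbind, lapply(1:10, function(i)
    somafilt:::build_read(ref$seq, 450 - 10 * (i - 1), "100M",
                          if (i %% 2) "+" else "-", 60, 35,
                          dup = i <= 2, secondary = i == 3)))
  bam <- write_synthetic_bam(reads, 2000, tempfile())
  obs <- collect_read_observations(bam, snv_site(pos = 450, contig = "synth1"))
  expect_equal(nrow(obs), 7L)
  # a site outside all reads yields an empty observation list
  expect_equal(nrow(collect_read_observations(
    bam, snv_site(pos = 1900, contig = "synth1"))), 0L)
  # absent contig is a fatal, named error
  expect_error(collect_read_observations(bam, snv_site(contig = "chrZ")),
               "chrZ.*absent")
})

test_that("deletions near and across the site are detected from the CIGAR", {
  ref <- make_reference(2000, 901)
  site <- 500L
  cases <- list(
    # cigar, expected base kind, expected near_indel
    list("43M3D57M", "base", TRUE),   # deletion 3 bp downstream of the site
    list("38M5D62M", "DEL", TRUE),    # deletion spanning the site itself
    list("61M3D39M", "base", FALSE),  # deletion 21 bp away: outside +/-5 bp
    list("100M", "base", FALSE))      # ungapped read
  for (cs in cases) {
    read <- somafilt:::build_read(ref$seq, site - 40L, cs[[1]], "+", 60, 35)
    bam <- write_synthetic_bam(read, 2000, tempfile())
    obs <- collect_read_observations(bam, snv_site(pos = site,
                                                   contig = "synth1"))
    expect_equal(nrow(obs), 1L, info = cs[[1]])
    expect_equal(obs$near_indel, cs[[3]], info = cs[[1]])
    if (cs[[2]] == "DEL") {
      expect_equal(obs$base, "DEL", info = cs[[1]])
      expect_true(is.na(obs$query_pos), info = cs[[1]])
      # the DEL read counts toward depth as 'other'
      rb <- substr(ref$seq, site, site)
      s <- summarize_site(obs, snv_site(
        pos = site, ref = rb,
        alt = setdiff(c("A", "C", "G", "T"), rb)[1], contig = "synth1"))
      expect_equal(s$depth, 1)
      expect_equal(s$other_count, 1)
    } else {
      expect_equal(obs$query_pos, 40L, info = cs[[1]])
      expect_equal(obs$base, substr(ref$seq, site, site), info = cs[[1]])
    }
  }
})

test_that("summary statistics match hand-computed values", {
  set.seed(31)
  site <- snv_site()
  # 10 ref observations, no alt: vaf 0, alt-conditioned stats NA
  obs <- random_observations(40)
  obs <- obs[obs$ref_match, , drop = FALSE][1:10, ]
  s <- summarize_site(obs, site)
  expect_equal(s$vaf, 0)
  expect_equal(s$alt_count, 0)
  expect_true(is.na(s$median_bq_alt))
  expect_true(is.na(s$mad_pos_alt))
  expect_true(is.na(s$improper_pair_frac_alt))

  # even-count median uses the midpoint convention
  obs <- random_observations(6)
  obs$alt_match <- TRUE; obs$ref_match <- FALSE; obs$base <- "T"
  obs$base_quality <- c(30, 31, 32, 33, 34, 35)
  s <- summarize_site(obs, site)
  expect_equal(s$median_bq_alt, 32.5)

  # MAD is unscaled; distance to read end uses the nearer end
  obs <- random_observations(4)
  obs$alt_match <- TRUE; obs$ref_match <- FALSE; obs$base <- "T"
  obs$query_pos <- c(40L, 41L, 42L, 43L)
  obs$read_length <- 100L
  s <- summarize_site(obs, site)
  expect_equal(s$mad_pos_alt, 1.0)
  expect_equal(s$median_dist_readend_alt, 41.5)
})

test_that("metric panel equals brute-force recomputation on 200 random pileups", {
  set.seed(4242)
  site <- snv_site()
  for (rep in 1:200) {
    obs <- random_observations(sample(0:60, 1))
    got <- summarize_site(obs, site)
    want <- oracle_summarize(obs, site)
    expect_equal(got[names(want)], want, tolerance = 0)
    # conservation invariant
    expect_equal(got$depth, got$ref_count + got$alt_count + got$other_count)
  }
})

test_that("non-SNV candidates get counts and VAF only", {
  ref <- make_reference(2000, 902)
  site <- 600L
  reads <- do.call(rbind, lapply(1:12, function(i)
    somafilt:::build_read(ref$seq, site - 20L - i, "100M",
                          if (i %% 2) "+" else "-", 60, 35)))
  bam <- write_synthetic_bam(reads, 2000, tempfile())
  refal <- substr(ref$seq, site, site + 1L)
  cand <- list(contig = "synth1", pos = site, ref = refal, alt = "A")
  obs <- collect_read_observations(bam, cand)
  s <- summarize_site(obs, cand)
  expect_equal(s$depth, 12)
  expect_equal(s$ref_count, 12)
  expect_true(is.na(s$median_bq_alt))
  expect_true(is.na(s$mq0_frac))
  expect_true(is.na(s$alt_fwd))
})

test_that("paired metrics are symmetric and recover planted parameters", {
  m <- shared_fixture("clean")
  tab <- shared_metrics("clean")
  sites <- manifest_sites(m)
  # planted clean somatic sites: tumor VAF near 0.4, normal clean
  expect_true(all(abs(tab$tumor_vaf - 0.4) < 0.2))
  expect_true(mean(abs(tab$tumor_vaf - 0.4)) < 0.06)
  expect_true(all(tab$normal_alt_count == 0))
  expect_true(all(tab$tumor_depth == sites$depth))

  # identical BAM as tumor and normal: field-for-field equality
  site <- sites[1, ]
  pm <- compute_pair_metrics(m$files$tumor_bam, m$files$tumor_bam, site)
  t_cols <- paste0("tumor_", somafilt:::sample_metric_names())
  n_cols <- paste0("normal_", somafilt:::sample_metric_names())
  expect_equal(unname(unlist(pm[t_cols])), unname(unlist(pm[n_cols])))

  # site outside all reads in both samples: both depths zero
  far <- snv_site(pos = as.integer(m$reference$length - 50), contig = "synth1")
  pm0 <- compute_pair_metrics(m$files$tumor_bam, m$files$normal_bam, far)
  expect_equal(pm0$tumor_depth, 0)
  expect_equal(pm0$normal_depth, 0)
  expect_true(is.na(pm0$tumor_vaf))
})

test_that("measured VAF tracks the planted VAF within binomial error", {
  # 48 sweep sites at VAF 0.40 equivalent check: use clean (20 sites at 0.4)
  # plus artifact-suite true sites for >=44 seeded draws at depth 80
  tab1 <- shared_metrics("clean")
  m2 <- shared_fixture("artifact_suite")
  tab2 <- shared_metrics("artifact_suite")
  s2 <- manifest_sites(m2)
  v2 <- tab2$tumor_vaf[s2$klass == "true_somatic" & s2$target_vaf == 0.4]
  vafs <- c(tab1$tumor_vaf, v2)
  expect_true(length(vafs) >= 25)
  expect_lt(mean(abs(vafs - 0.4)), 0.06)
})

test_that("chunked metrics cache resumes, is parallel-deterministic and guards staleness", {
  m <- shared_fixture("clean")
  cache <- tempfile()
  run1 <- suppressMessages(run_metrics_stage(
    m$files$vcf, m$files$tumor_bam, m$files$normal_bam, cache,
    jobs = 1, chunk_size = 5))
  expect_equal(attr(run1, "chunks_total"), 4L)
  expect_equal(attr(run1, "chunks_computed"), 4L)

  # second run reuses every chunk and reproduces the table exactly
  run2 <- suppressMessages(run_metrics_stage(
    m$files$vcf, m$files$tumor_bam, m$files$normal_bam, cache,
    jobs = 1, chunk_size = 5))
  expect_equal(attr(run2, "chunks_computed"), 0L)
  expect_equal(attr(run2, "chunks_reused"), 4L)
  expect_identical(tab_df(run1), tab_df(run2))

  # deleting one chunk recomputes exactly that chunk
  file.remove(file.path(cache, "metrics.2.tsv.gz"))
  run3 <- suppressMessages(run_metrics_stage(
    m$files$vcf, m$files$tumor_bam, m$files$normal_bam, cache,
    jobs = 1, chunk_size = 5))
  expect_equal(attr(run3, "chunks_computed"), 1L)
  expect_identical(tab_df(run3), tab_df(run1))

  # jobs=1 and jobs=4 give identical tables
  run4 <- suppressMessages(run_metrics_stage(
    m$files$vcf, m$files$tumor_bam, m$files$normal_bam, tempfile(),
    jobs = 4, chunk_size = 5))
  expect_identical(tab_df(run4), tab_df(run1))

  # fingerprint mismatch triggers recomputation with a warning
  fp <- file.path(cache, "fingerprint.json")
  j <- jsonlite::read_json(fp)
  j$record_count <- 9999
  jsonlite::write_json(j, fp, auto_unbox = TRUE)
  expect_warning(
    run5 <- suppressMessages(run_metrics_stage(
      m$files$vcf, m$files$tumor_bam, m$files$normal_bam, cache,
      jobs = 1, chunk_size = 5)),
    "fingerprint mismatch")
  expect_equal(attr(run5, "chunks_computed"), 4L)
})

test_that("contig naming mismatch between VCF and BAMs is fatal up front", {
  m <- shared_fixture("clean")
  p <- write_tiny_vcf("chr1\t100\t.\tA\tT\t.\t.\t.")
  expect_error(
    suppressMessages(run_metrics_stage(p, m$files$tumor_bam,
                                       m$files$normal_bam, tempfile())),
    "contig naming mismatch")
})
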