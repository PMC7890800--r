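# A metrics row that passes every default filter, for perturbation tests.
clean_metrics_row <- function() {
  row <- list(contig = "chr1", pos = 100L, ref = "A", alt = "T",
              tumor_depth = 80, tumor_ref_count = 48, tumor_alt_count = 32,
              tumor_other_count = 0, tumor_vaf = 0.4,
              tumor_median_bq_alt = 35, tumor_median_bq_ref = 35,
              tumor_median_mq_alt = 60, tumor_median_mq_all = 60,
              tumor_alt_fwd = 16, tumor_alt_rev = 16,
              tumor_ref_fwd = 24, tumor_ref_rev = 24,
              tumor_median_dist_readend_alt = 40, tumor_mad_pos_alt = 20,
              tumor_softclip_frac_alt = 0, tumor_mean_excess_nm_alt = 0,
              tumor_mq0_frac = 0, tumor_near_indel_frac = 0,
              tumor_improper_pair_frac_alt = 0,
              normal_depth = 80, normal_ref_count = 80, normal_alt_count = 0,
              normal_other_count = 0, normal_vaf = 0,
              normal_median_bq_alt = NA_real_, normal_median_bq_ref = 35,
              normal_median_mq_alt = NA_real_, normal_median_mq_all = 60,
              normal_alt_fwd = 0, normal_alt_rev = 0,
              normal_ref_fwd = 40, normal_ref_rev = 40,
              normal_median_dist_readend_alt = NA_real_,
              normal_mad_pos_alt = NA_real_,
              normal_softclip_frac_alt = NA_real_,
              normal_mean_excess_nm_alt = NA_real_, normal_mq0_frac = 0,
              normal_near_indel_frac = 0,
              normal_improper_pair_frac_alt = NA_real_)
  df <- as.data.frame(row, stringsAsFactors = FALSE)
  structure(df[, metrics_columns()],
            class = c("somafilt_metrics", "data.frame"))
}

test_that("threshold comparisons are strict with equality passing", {
  row <- clean_metrics_row()
  row$tumor_vaf <- 0.02
  expect_equal(evaluate_filter("min_vaf_tumor", 0.05, row), "fail")
  row$tumor_vaf <- 0.05
  expect_equal(evaluate_filter("min_vaf_tumor", 0.05, row), "pass")
  row$normal_vaf <- 0.03
  expect_equal(evaluate_filter("max_vaf_normal", 0.03, row), "pass")
  row$normal_vaf <- 0.031
  expect_equal(evaluate_filter("max_vaf_normal", 0.03, row), "fail")
  expect_error(evaluate_filter("no_such_filter", 1, row), "unknown filter")
})

test_that("NA metrics resolve by policy; strand filter needs 10 alt reads", {
  row <- clean_metrics_row()
  row$tumor_alt_count <- 0
  row$tumor_median_bq_alt <- NA_real_
  expect_equal(evaluate_filter("min_median_bq_alt_tumor", 30, row), "fail")
  expect_equal(evaluate_filter("strand_minor_frac_alt_tumor", 0.05, row),
               "not_applicable")
  row <- clean_metrics_row()
  row$tumor_alt_count <- 9
  expect_equal(evaluate_filter("strand_minor_frac_alt_tumor", 0.05, row),
               "not_applicable")
  row$tumor_alt_count <- 10
  row$tumor_alt_fwd <- 10; row$tumor_alt_rev <- 0
  expect_equal(evaluate_filter("strand_minor_frac_alt_tumor", 0.05, row),
               "fail")
})

test_that("apply_filters covers the table in order with a pure overall verdict", {
  tab <- rbind(clean_metrics_row(), clean_metrics_row(), clean_metrics_row())
  tab$pos <- c(100L, 200L, 300L)
  tab$tumor_vaf[2] <- 0.01
  tab$tumor_median_bq_alt[2] <- 10
  class(tab) <- c("somafilt_metrics", "data.frame")
  v <- apply_filters(default_preset(), tab)
  expect_equal(v$pos, tab$pos)
  expect_equal(v$overall, c("pass", "fail", "pass"))
  # the failing variant fails exactly the two perturbed filters
  nms <- default_preset()$entries$name
  failed <- nms[vapply(nms, function(f) v[[f]][2] == "fail", logical(1))]
  expect_setequal(failed, c("min_vaf_tumor", "min_median_bq_alt_tumor"))
  # missing metric column is a version-mismatch error
  tab2 <- tab; tab2$tumor_vaf <- NULL
  expect_error(apply_filters(default_preset(), tab2), "version mismatch")
})

test_that("an empty config passes everything, with no per-filter entries", {
  tab <- clean_metrics_row()
  tab$tumor_vaf <- 0.001  # would fail under any real preset
  cfg <- somafilt:::new_filter_config(character(0), numeric(0), "user")
  v <- apply_filters(cfg, tab)
  expect_equal(v$overall, "pass")
  expect_equal(ncol(v), 5L)  # key columns + overall only
})

test_that("verdicts are idempotent and invariant to filter order", {
  tab <- shared_metrics("artifact_suite")
  cfg <- default_preset()
  v1 <- apply_filters(cfg, tab)
  v2 <- apply_filters(cfg, tab)
  expect_identical(as.data.frame(v1), as.data.frame(v2))
  set.seed(9)
  perm <- sample(nrow(cfg$entries))
  cfg_p <- somafilt:::new_filter_config(cfg$entries$name[perm],
                                        cfg$entries$threshold[perm], "user")
  v3 <- apply_filters(cfg_p, tab)
  expect_equal(v3$overall, v1$overall)
  for (nm in cfg$entries$name) expect_equal(v3[[nm]], v1[[nm]])
})

test_that("raising a min threshold never increases the pass count", {
  tab <- shared_metrics("vaf_sweep")
  passes <- vapply(seq(0.01, 0.20, by = 0.01), function(th) {
    cfg <- default_preset()
    cfg$entries$threshold[cfg$entries$name == "min_vaf_tumor"] <- th
    sum(apply_filters(cfg, tab)$overall == "pass")
  }, numeric(1))
  expect_true(all(diff(passes) <= 0))
  # and lowering below any observed VAF passes at least as many as default
  cfg0 <- default_preset()
  cfg0$entries$threshold[cfg0$entries$name == "min_vaf_tumor"] <- 0
  expect_gte(sum(apply_filters(cfg0, tab)$overall == "pass"),
             max(passes))
})

test_that("summaries conserve counts and write TSV plus plot", {
  tab <- shared_metrics("artifact_suite")
  v <- apply_filters(default_preset(), tab)
  out <- tempfile()
  s <- summarize_and_plot(v, out)
  expect_equal(s$total, nrow(tab))
  for (i in seq_len(nrow(s$summary)))
    expect_equal(s$summary$pass[i] + s$summary$fail[i] +
                 s$summary$not_applicable[i], s$total)
  expect_true(file.exists(s$tsv))
  back <- read.delim(s$tsv)
  expect_equal(nrow(back), nrow(default_preset()$entries))
  expect_equal(back$pass + back$fail + back$not_applicable,
               rep(s$total, nrow(back)))

  # all-pass verdicts: every filter shows pass == total, fail == 0
  clean_tab <- shared_metrics("clean")
  vc <- apply_filters(default_preset(), clean_tab)
  sc <- summarize_and_plot(vc, tempfile())
  expect_true(all(sc$summary$fail == 0))
  expect_true(all(sc$summary$pass + sc$summary$not_applicable == sc$total))
})

test_that("per-class fail counts match the fixture manifest", {
  m <- shared_fixture("artifact_suite")
  tab <- shared_metrics("artifact_suite")
  sites <- manifest_sites(m)
  v <- apply_filters(default_preset(), tab)
  for (klass in names(somafilt:::artifact_classes())) {
    f <- somafilt:::artifact_classes()[[klass]]
    idx <- which(sites$klass == klass)
    expect_true(all(v[[f]][idx] == "fail"),
                info = paste(klass, "must fail", f))
  }
})
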