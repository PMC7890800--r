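# Independent brute-force recomputation of the per-sample metric panel.
# Deliberately re-derives every count, median and MAD by exhaustive
# iteration over the raw observation list, sharing no code with
# summarize_site().

oracle_median <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n == 0) return(NA_real_)
  s <- sort(x)
  if (n %% 2 == 1) as.numeric(s[(n + 1) / 2]) else (s[n / 2] + s[n / 2 + 1]) / 2
}

oracle_summarize <- function(obs, site) {
  depth <- nrow(obs)
  alt_idx <- integer(0); ref_idx <- integer(0)
  for (i in seq_len(depth)) {
    if (obs$alt_match[i]) alt_idx <- c(alt_idx, i)
    else if (obs$ref_match[i]) ref_idx <- c(ref_idx, i)
  }
  na_count <- length(alt_idx)
  dist_end <- numeric(0)
  for (i in alt_idx)
    dist_end <- c(dist_end, min(obs$query_pos[i],
                                obs$read_length[i] - 1 - obs$query_pos[i]))
  alt_qp <- obs$query_pos[alt_idx]
  mad <- if (na_count == 0) NA_real_ else {
    m <- oracle_median(alt_qp)
    devs <- numeric(0)
    for (q in alt_qp) devs <- c(devs, abs(q - m))
    oracle_median(devs)
  }
  excess <- numeric(0)
  for (i in alt_idx) if (!is.na(obs$nm[i]))
    excess <- c(excess, max(obs$nm[i] - 1, 0))
  list(
    depth = depth,
    ref_count = length(ref_idx),
    alt_count = na_count,
    other_count = depth - length(ref_idx) - na_count,
    vaf = if (depth == 0) NA_real_ else na_count / depth,
    median_bq_alt = if (na_count == 0) NA_real_ else
      oracle_median(obs$base_quality[alt_idx]),
    median_bq_ref = if (length(ref_idx) == 0) NA_real_ else
      oracle_median(obs$base_quality[ref_idx]),
    median_mq_alt = if (na_count == 0) NA_real_ else
      oracle_median(obs$mapping_quality[alt_idx]),
    median_mq_all = if (depth == 0) NA_real_ else
      oracle_median(obs$mapping_quality),
    alt_fwd = sum(obs$strand[alt_idx] == "+"),
    alt_rev = sum(obs$strand[alt_idx] == "-"),
    ref_fwd = sum(obs$strand[ref_idx] == "+"),
    ref_rev = sum(obs$strand[ref_idx] == "-"),
    median_dist_readend_alt = if (na_count == 0) NA_real_ else
      oracle_median(dist_end),
    mad_pos_alt = mad,
    softclip_frac_alt = if (na_count == 0) NA_real_ else
      sum(obs$has_softclip[alt_idx]) / na_count,
    mean_excess_nm_alt = if (na_count == 0 || length(excess) == 0) NA_real_
      else sum(excess) / length(excess),
    mq0_frac = if (depth == 0) NA_real_ else
      sum(obs$mapping_quality == 0) / depth,
    near_indel_frac = if (depth == 0) NA_real_ else
      sum(obs$near_indel) / depth,
    improper_pair_frac_alt = if (na_count == 0) NA_real_ else
      sum(!obs$properly_paired[alt_idx]) / na_count)
}
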