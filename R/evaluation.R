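#' Match passing calls against a truth set
#'
#' A call matches a truth variant iff `contig`, `pos`, `ref` and `alt` are
#' all equal -- exact position and exact allele, no distance window and no
#' normalization (the package's scope is SNVs, where windowing has nothing
#' to add). Duplicate sites within either set are collapsed before counting.
#'
#' @param passing_calls,truth_calls Data frames with columns `contig`,
#'   `pos`, `ref`, `alt`.
#' @return A list of confusion counts: `TP` (passing calls present in
#'   truth), `FP` (passing calls absent from truth), `FN` (truth variants
#'   not among the passing calls).
#' @details If both sets are non-empty but share no contig names, a warning
#'   about likely reference-naming mismatch ("chr1" vs "1") is raised;
#'   counts are still computed.
#' @export
match_truth <- function(passing_calls, truth_calls) {
  key <- function(df) {
    if (nrow(df) == 0L) return(character(0))
    unique(paste(df$contig, df$pos, toupper(df$ref), toupper(df$alt),
                 sep = ":"))
  }
  p <- key(passing_calls)
  t <- key(truth_calls)
  if (nrow(passing_calls) > 0L && nrow(truth_calls) > 0L &&
      length(intersect(unique(passing_calls$contig),
                       unique(truth_calls$contig))) == 0L)
    warning("no contig names shared between calls and truth; ",
            "check reference naming (e.g. 'chr1' vs '1')", call. = FALSE)
  list(TP = length(intersect(p, t)),
       FP = length(setdiff(p, t)),
       FN = length(setdiff(t, p)))
}

#' Recall, precision and F1 from confusion counts
#'
#' Recall = TP/(TP+FN), the proportion of true variants recovered after
#' filtering. Precision = TP/(TP+FP), the proportion of reported variants
#' that are true. F1 = 2TP/(2TP+FP+FN), the harmonic mean of the two. All
#' range over \[0, 1\]; any 0/0 ratio is reported as `NA` (scoring an empty
#' set is undefined, not zero).
#'
#' @param counts List or numeric vector with elements `TP`, `FP`, `FN`
#'   (all non-negative).
#' @return A list of class `somafilt_evaluation`: `counts`, `recall`,
#'   `precision`, `f1`.
#' @export
score_confusion <- function(counts) {
  tp <- as.numeric(counts[["TP"]])
  fp <- as.numeric(counts[["FP"]])
  fn <- as.numeric(counts[["FN"]])
  if (any(is.na(c(tp, fp, fn))) || any(c(tp, fp, fn) < 0))
    stop("confusion counts must be non-negative", call. = FALSE)
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  structure(list(
    counts = list(TP = tp, FP = fp, FN = fn),
    recall = ratio(tp, tp + fn),
    precision = ratio(tp, tp + fp),
    f1 = ratio(2 * tp, 2 * tp + fp + fn)),
    class = "somafilt_evaluation")
}

#' Harmonic-mean F1 from a (recall, precision) pair
#'
#' @param recall,precision Values in \[0, 1\].
#' @return `2 * precision * recall / (precision + recall)`; `NA` when both
#'   are zero.
#' @export
f1_score <- function(recall, precision) {
  if (is.na(recall) || is.na(precision)) return(NA_real_)
  if (recall + precision == 0) return(NA_real_)
  2 * precision * recall / (precision + recall)
}

#' Evaluate passing calls against a truth set
#'
#' Convenience wrapper: [match_truth()] then [score_confusion()].
#'
#' @param passing_calls,truth_calls Data frames with `contig`, `pos`,
#'   `ref`, `alt`. When evaluating a filtered VCF, pass only its `PASS`
#'   records. Note that if the truth set contains variants the upstream
#'   caller never reported, those count as FN of the combined
#'   caller-plus-filtering pipeline, not of the filtering step alone.
#' @return A `somafilt_evaluation` (see [score_confusion()]).
#' @export
evaluate_calls <- function(passing_calls, truth_calls) {
  score_confusion(match_truth(passing_calls, truth_calls))
}

#' @export
print.somafilt_evaluation <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "NA" else sprintf("%.4f", v)
  cat(sprintf("TP=%d FP=%d FN=%d | recall=%s precision=%s F1=%s\n",
              x$counts$TP, x$counts$FP, x$counts$FN,
              fmt(x$recall), fmt(x$precision), fmt(x$f1)))
  invisible(x)
}

#' Write an evaluation summary as TSV
#'
#' @param evaluation A `somafilt_evaluation`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_evaluation <- function(evaluation, path) {
  df <- data.frame(TP = evaluation$counts$TP, FP = evaluation$counts$FP,
                   FN = evaluation$counts$FN, recall = evaluation$recall,
                   precision = evaluation$precision, f1 = evaluation$f1)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}
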