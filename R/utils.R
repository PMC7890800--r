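#' Tool version string
#'
#' Version recorded in metric-cache fingerprints, VCF provenance headers and
#' run logs. Changing the package version invalidates cached metrics.
#'
#' @return A single character string, e.g. `"somafilt 0.1.0"`.
#' @export
somafilt_version <- function() {
  paste("somafilt", as.character(utils::packageVersion("somafilt")))
}

# Run expr with a temporarily-seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Deterministic per-locus sub-seed, kept within 32-bit integer range.
locus_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 10007 + as.numeric(index) * 101) %% 2147483647)
}

# Unscaled median absolute deviation (no 1.4826 consistency factor).
mad_unscaled <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(NA_real_)
  stats::median(abs(x - stats::median(x)))
}

# Median that returns NA_real_ for empty input (after NA removal).
median_or_na <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(NA_real_)
  as.numeric(stats::median(x))
}

# Plain-text, level-tagged run log: one event per line.
log_open <- function(path) {
  con <- file(path, open = "wt")
  con
}

log_line <- function(con, level, msg) {
  line <- sprintf("%s [%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  level, msg)
  if (!is.null(con)) writeLines(line, con)
  message(line)
  invisible(line)
}
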