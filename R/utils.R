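# internal helpers: argument checks and TSV exchange (UTF-8, '.' decimal,
# header row; the single dialect every stage reads and writes)

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_number <- function(x, name, min = -Inf, strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stopf("'%s' must be a single non-missing number", name)
  if (strict_min && x <= min) stopf("'%s' must be > %g (got %g)", name, min, x)
  if (!strict_min && x < min) stopf("'%s' must be >= %g (got %g)", name, min, x)
  invisible(x)
}

#' Read a TSV table and validate its schema
#'
#' All pipeline exchange files are UTF-8 tab-separated tables with a header
#' row. Missing columns are reported by file and column name.
#'
#' @param path file path.
#' @param required character vector of required column names.
#' @return a `data.frame`.
#' @export
read_tsv_checked <- function(path, required = character()) {
  if (!file.exists(path)) stopf("input file not found: %s", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stopf("file '%s' is missing required column(s): %s",
          path, paste(missing, collapse = ", "))
  df
}

#' Write a table in the pipeline's TSV dialect
#'
#' @param df data.frame to write.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

# mean +- sample sd aggregation used for every replicate summary
aggregate_replicates <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) stopf("no replicate values to aggregate")
  list(mean = mean(x), sd = if (length(x) > 1L) stats::sd(x) else 0, n = length(x))
}

# lognormal multiplier with unit mean and coefficient of variation cv
rlnorm_cv <- function(n, cv) {
  if (cv < 0) stopf("noise CV must be >= 0 (got %g)", cv)
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}
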