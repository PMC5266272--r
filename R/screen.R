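#' Classify a screened gene as dosage-compensated
#'
#' A gene is called compensated when its mean protein fold change under
#' copy-number increase is at or below `protein_threshold` while its mean
#' endogenous mRNA fold change stays inside `mrna_band` -- the
#' post-transcriptional criterion: protein goes down although mRNA from the
#' endogenous locus does not. A protein fold above the threshold is
#' uncompensated; a protein reduction accompanied by an mRNA change outside
#' the band is indeterminate (the reduction may be transcriptional).
#'
#' @param protein_folds per-replicate protein fold changes (>= 2 values).
#' @param mrna_folds per-replicate mRNA fold changes (may be empty, in which
#'   case a protein reduction cannot be confirmed post-transcriptional and
#'   the call is indeterminate).
#' @param protein_threshold maximum mean protein fold for a compensated call
#'   (default 0.7; the screen's hits all fall at or below 0.6).
#' @param mrna_band closed interval of acceptable mean mRNA folds
#'   (default `c(0.7, 1.4)`, encoding "mRNA did not change").
#' @return one of `"compensated"`, `"uncompensated"`, `"indeterminate"`.
#' @examples
#' classify_gene(c(0.3, 0.35, 0.4), c(1.0, 1.1, 0.9))
#' @export
classify_gene <- function(protein_folds, mrna_folds = numeric(),
                          protein_threshold = 0.7,
                          mrna_band = c(0.7, 1.4)) {
  if (!length(protein_folds)) stopf("protein_folds must be nonempty")
  if (length(protein_folds) < 2L)
    stopf("classification requires >= 2 protein replicates")
  if (mean(protein_folds) > protein_threshold) return("uncompensated")
  if (!length(mrna_folds)) return("indeterminate")
  m <- mean(mrna_folds)
  if (m >= mrna_band[1] && m <= mrna_band[2]) "compensated" else "indeterminate"
}

#' Exact one-tailed Mann-Whitney rank-sum test
#'
#' Computes the one-tailed p-value of the rank-sum statistic by complete
#' enumeration of all choose(n_x + n_y, n_x) group assignments of the pooled
#' observed values, the exact reference distribution for the small designs
#' (n = 3--6 per group) typical of blot-quantification experiments. Ties are
#' handled by permuting the observed values themselves. For total sample
#' sizes above `exact_limit` the normal approximation with tie correction is
#' used instead.
#'
#' @param x,y numeric vectors, both nonempty.
#' @param alternative `"y_greater"` (y stochastically greater than x) or
#'   `"x_greater"`.
#' @param exact_limit maximum `length(x) + length(y)` for exact enumeration
#'   (default 12).
#' @return p-value in (0, 1].
#' @examples
#' mann_whitney_exact(c(1, 2, 3), c(4, 5, 6), "y_greater") # 1/20 = 0.05
#' @export
mann_whitney_exact <- function(x, y,
                               alternative = c("y_greater", "x_greater"),
                               exact_limit = 12L) {
  alternative <- match.arg(alternative)
  if (!length(x) || !length(y)) stopf("both groups must be nonempty")
  if (alternative == "x_greater") { tmp <- x; x <- y; y <- tmp }
  pooled <- c(x, y)
  n <- length(pooled); ny <- length(y)
  r <- rank(pooled)
  w_obs <- sum(r[seq.int(length(x) + 1L, n)])
  if (n <= exact_limit) {
    idx <- utils::combn(n, ny)
    w_all <- colSums(matrix(r[idx], nrow = ny))
    # >= with a numeric-noise guard: midranks are multiples of 1/2
    sum(w_all >= w_obs - 1e-9) / ncol(idx)
  } else {
    nx <- length(x)
    u <- w_obs - ny * (ny + 1) / 2
    mu <- nx * ny / 2
    tie_tab <- table(pooled)
    sigma2 <- nx * ny / 12 *
      ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
    z <- (u - mu - 0.5) / sqrt(sigma2)
    min(1, stats::pnorm(z, lower.tail = FALSE))
  }
}

#' Pearson chi-square test for a 2x2 table
#'
#' @param a,b,c,d cell counts of the table `rbind(c(a, b), c(c, d))`.
#' @param yates apply the Yates continuity correction (default `FALSE`).
#' @return list with `statistic` (df = 1) and `p`.
#' @examples
#' chi2_2x2(5, 49, 7, 5)
#' @export
chi2_2x2 <- function(a, b, c, d, yates = FALSE) {
  counts <- c(a, b, c, d)
  if (any(counts < 0)) stopf("counts must be >= 0")
  n <- sum(counts)
  if (n == 0) stopf("table total must be > 0")
  marg <- c(a + b, c + d, a + c, b + d)
  if (any(marg == 0)) stopf("a zero marginal makes the chi-square undefined")
  dev <- abs(a * d - b * c)
  if (yates) dev <- max(0, dev - n / 2)
  stat <- n * dev^2 / prod(marg)
  list(statistic = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Aggregate screen classifications by protein complex
#'
#' Builds the per-complex report of tested versus compensated subunits.
#' Counts may come from classified screen records, or be supplied directly
#' as `n_tested`/`n_compensated` columns of `complexes` (the form a printed
#' summary table takes).
#'
#' @param records optional data.frame with columns `gene`, `complex_id`,
#'   `classification`; rows with `complex_id` `NA` are ignored. A record is
#'   tested when it carries any classification and compensated when the
#'   classification is `"compensated"`.
#' @param complexes data.frame with columns `complex_id`, `n_subunits`, and,
#'   when `records` is `NULL`, `n_tested` and `n_compensated`.
#' @return object of class `complex_report`: the per-complex data.frame with
#'   attributes `total_tested`, `total_compensated` and
#'   `percent_compensated` (integer percentage, rounded down).
#' @export
summarize_complexes <- function(records = NULL, complexes) {
  if (!all(c("complex_id", "n_subunits") %in% names(complexes)))
    stopf("complexes table needs columns complex_id and n_subunits")
  if (is.null(records)) {
    if (!all(c("n_tested", "n_compensated") %in% names(complexes)))
      stopf("without records, complexes must carry n_tested and n_compensated")
    rep_df <- complexes[c("complex_id", "n_subunits", "n_tested", "n_compensated")]
  } else {
    rec <- records[!is.na(records$complex_id), , drop = FALSE]
    unknown <- setdiff(rec$complex_id, complexes$complex_id)
    if (length(unknown))
      stopf("records reference unknown complex_id(s): %s",
            paste(unknown, collapse = ", "))
    rep_df <- complexes[c("complex_id", "n_subunits")]
    rep_df$n_tested <- vapply(rep_df$complex_id, function(id)
      sum(rec$complex_id == id & !is.na(rec$classification)), integer(1))
    rep_df$n_compensated <- vapply(rep_df$complex_id, function(id)
      sum(rec$complex_id == id & rec$classification == "compensated",
          na.rm = TRUE), integer(1))
  }
  bad <- rep_df$n_compensated > rep_df$n_tested |
    rep_df$n_tested > rep_df$n_subunits
  if (any(bad))
    stopf("inconsistent counts (compensated > tested or tested > subunits) for: %s",
          paste(rep_df$complex_id[bad], collapse = ", "))
  tot_t <- sum(rep_df$n_tested); tot_c <- sum(rep_df$n_compensated)
  structure(rep_df,
            total_tested = tot_t,
            total_compensated = tot_c,
            percent_compensated = if (tot_t > 0) floor(100 * tot_c / tot_t) else 0L,
            class = c("complex_report", "data.frame"))
}

#' @export
print.complex_report <- function(x, ...) {
  cat("Complex-subunit compensation report\n")
  print.data.frame(x, row.names = FALSE)
  cat(sprintf("Total: %d of %d tested subunits compensated (%d%%)\n",
              attr(x, "total_compensated"), attr(x, "total_tested"),
              attr(x, "percent_compensated")))
  invisible(x)
}

#' Classify every record of a screen table
#'
#' Applies [classify_gene()] to a long-format screen table of per-replicate
#' protein and mRNA fold changes.
#'
#' @param folds data.frame with columns `gene`, `kind`
#'   (`protein`/`mrna`), `fold`, `replicate`; optionally `complex_id`.
#' @param protein_threshold,mrna_band passed to [classify_gene()].
#' @return data.frame with one row per gene: `gene`, `complex_id` (if
#'   present), mean folds and `classification`.
#' @export
classify_screen <- function(folds, protein_threshold = 0.7,
                            mrna_band = c(0.7, 1.4)) {
  req <- c("gene", "kind", "fold")
  missing <- setdiff(req, names(folds))
  if (length(missing))
    stopf("folds table is missing column(s): %s", paste(missing, collapse = ", "))
  out <- lapply(unique(folds$gene), function(g) {
    fg <- folds[folds$gene == g, , drop = FALSE]
    pf <- fg$fold[fg$kind == "protein"]
    mf <- fg$fold[fg$kind == "mrna"]
    data.frame(
      gene = g,
      complex_id = if ("complex_id" %in% names(fg))
        fg$complex_id[1] else NA_character_,
      protein_fold = mean(pf),
      mrna_fold = if (length(mf)) mean(mf) else NA_real_,
      classification = classify_gene(pf, mf, protein_threshold, mrna_band))
  })
  do.call(rbind, out)
}
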