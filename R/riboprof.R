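#' A-site offset for a read length
#'
#' Maps a read length to the distance from its 5' end to the ribosomal
#' A-site. Ribosome footprints of 26--30 nt use the linear map
#' `length - 13` (26 -> 13 through 30 -> 17); mRNA fragments of 22--51 nt
#' use a fixed offset of 15 nt. Other lengths are rejected (`NA`), and
#' rejected reads contribute nothing to counting. An explicit
#' `offset_table` overrides the footprint mapping.
#'
#' @param length read length(s) in nt.
#' @param read_class `"footprint"` or `"mrna_fragment"`.
#' @param offset_table optional data.frame with columns `length`, `offset`
#'   replacing the built-in footprint mapping.
#' @return integer offset(s) in nt, `NA` for rejected lengths.
#' @examples
#' asite_offset(28, "footprint")      # 15
#' asite_offset(31, "footprint")      # NA: rejected
#' asite_offset(40, "mrna_fragment")  # 15
#' @export
asite_offset <- function(length, read_class, offset_table = NULL) {
  if (any(length <= 0)) stopf("read length must be > 0")
  read_class <- match.arg(read_class, c("footprint", "mrna_fragment"))
  if (read_class == "mrna_fragment")
    return(ifelse(length >= 22 & length <= 51, 15L, NA_integer_))
  if (!is.null(offset_table)) {
    i <- match(length, offset_table$length)
    return(as.integer(offset_table$offset[i]))
  }
  ifelse(length >= 26 & length <= 30, as.integer(length - 13L), NA_integer_)
}

validate_cds <- function(cds) {
  len <- cds$cds_end - cds$cds_start
  if (is.na(len) || len <= 0 || len %% 3 != 0)
    stopf("malformed CDS for %s: length %s is not a positive multiple of 3",
          cds$transcript_id, len)
  if (len < 3 * (15 + 5 + 1))
    stopf("CDS for %s too short to count: %d nt < 63 nt (15 + 5 excluded codons plus one countable codon)",
          cds$transcript_id, len)
  invisible(cds)
}

#' Countable CDS window and effective length
#'
#' The counting window excludes the first 15 and last 5 codons:
#' A-site positions in `[cds_start + 45, cds_end - 15)` (0-based, half-open)
#' are countable. The effective length is the width of that window.
#'
#' @param cds list or one-row data.frame with `transcript_id`, `cds_start`
#'   (0-based inclusive), `cds_end` (exclusive).
#' @return list with `start`, `end` (half-open window) and `effective_length`.
#' @export
countable_window <- function(cds) {
  validate_cds(cds)
  s <- cds$cds_start + 45L
  e <- cds$cds_end - 15L
  list(start = s, end = e, effective_length = e - s)
}

#' Count reads on a gene by A-site position
#'
#' Assigns each read an A-site position `five_prime + asite_offset(length)`
#' and counts those falling in the countable window of the CDS (first 15
#' and last 5 codons excluded). Reads with rejected lengths contribute 0.
#'
#' @param reads data.frame with columns `transcript_id`, `five_prime`
#'   (0-based transcript coordinate), `length`, `read_class`.
#' @param cds CDS annotation as in [countable_window()].
#' @param offset_table optional footprint offset override
#'   (see [asite_offset()]).
#' @return integer read count.
#' @export
count_gene <- function(reads, cds, offset_table = NULL) {
  win <- countable_window(cds)
  reads <- reads[reads$transcript_id == cds$transcript_id, , drop = FALSE]
  if (!nrow(reads)) return(0L)
  if (any(reads$five_prime < 0)) stopf("five_prime coordinates must be >= 0")
  off <- rep(NA_integer_, nrow(reads))
  for (cls in unique(reads$read_class)) {
    i <- reads$read_class == cls
    off[i] <- asite_offset(reads$length[i], cls, offset_table)
  }
  asite <- reads$five_prime + off
  sum(!is.na(asite) & asite >= win$start & asite < win$end)
}

#' Median-of-ratios size factors
#'
#' Per-sample normalization factors: for each gene with nonzero counts in
#' every sample, the ratio of its count to its geometric mean across
#' samples; the size factor is the median of these ratios per sample.
#'
#' @param counts genes x samples count matrix (>= 1 gene nonzero in all
#'   samples).
#' @return numeric vector of per-sample factors (all 1 for a single-sample
#'   matrix).
#' @examples
#' m <- cbind(s1 = c(10, 20, 30), s2 = c(20, 40, 60))
#' size_factors(m) # ratio 2 between samples
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stopf("counts must be >= 0")
  if (ncol(counts) == 1L) return(setNames(1, colnames(counts)))
  keep <- rowSums(counts == 0) == 0
  if (!any(keep))
    stopf("size factors undefined: no gene has nonzero counts in all samples")
  logc <- log(counts[keep, , drop = FALSE])
  loggeo <- rowMeans(logc)
  apply(logc, 2, function(x) exp(stats::median(x - loggeo)))
}

#' Translational-efficiency fold changes between conditions
#'
#' For each replicate pair (Single vs Multi), computes the size-factor
#' normalized mRNA fold change, the ribosome-density fold change (footprint
#' count per countable CDS nt), and the translational-efficiency fold
#' `te_fold = density_fold / mrna_fold`; per-gene folds are averaged across
#' replicate pairs. Effective lengths cancel in both folds, so TE folds do
#' not depend on them. Genes with a zero count in any Single-condition
#' replicate are flagged and reported with `NA` folds rather than dropped,
#' unless a `pseudocount` is supplied.
#'
#' @param fp genes x samples footprint count matrix (column names are
#'   sample ids).
#' @param rna genes x samples mRNA count matrix, same genes.
#' @param design data.frame with columns `sample`, `condition`
#'   (`single`/`multi`), `replicate`, covering the columns of both matrices
#'   (footprint and RNA libraries of a replicate share the `replicate` id).
#' @param effective_lengths optional named vector of countable CDS lengths
#'   (nt) per gene; defaults to 1 for every gene since lengths cancel.
#' @param pseudocount added to every count before forming ratios
#'   (default 0: no pseudocounts).
#' @return data.frame with `gene`, `mrna_fold`, `te_fold`, `flagged`.
#' @export
te_fold_change <- function(fp, rna, design, effective_lengths = NULL,
                           pseudocount = 0) {
  fp <- as.matrix(fp); rna <- as.matrix(rna)
  if (!identical(rownames(fp), rownames(rna)))
    stopf("footprint and RNA matrices must cover the same genes in order")
  req <- c("sample", "condition", "replicate")
  missing <- setdiff(req, names(design))
  if (length(missing))
    stopf("design table is missing column(s): %s", paste(missing, collapse = ", "))
  genes <- rownames(fp)
  if (is.null(effective_lengths))
    effective_lengths <- setNames(rep(1, length(genes)), genes)

  norm <- function(mat) {
    sf <- size_factors(mat)
    sweep(mat + pseudocount, 2, sf, "/")
  }
  fp_n <- norm(fp); rna_n <- norm(rna)

  pair_cols <- function(mat) {
    d <- design[design$sample %in% colnames(mat), , drop = FALSE]
    reps <- intersect(d$replicate[d$condition == "single"],
                      d$replicate[d$condition == "multi"])
    if (!length(reps)) stopf("design has no matched single/multi replicate pair")
    lapply(sort(reps), function(r) list(
      single = d$sample[d$condition == "single" & d$replicate == r],
      multi = d$sample[d$condition == "multi" & d$replicate == r]))
  }
  fp_pairs <- pair_cols(fp_n); rna_pairs <- pair_cols(rna_n)
  if (length(fp_pairs) != length(rna_pairs))
    stopf("footprint and RNA designs have different replicate pairings")

  mrna_mat <- sapply(seq_along(rna_pairs), function(i) {
    p <- rna_pairs[[i]]
    rna_n[, p$multi] / rna_n[, p$single]
  })
  dens_mat <- sapply(seq_along(fp_pairs), function(i) {
    p <- fp_pairs[[i]]
    (fp_n[, p$multi] / effective_lengths[genes]) /
      (fp_n[, p$single] / effective_lengths[genes])
  })
  te_mat <- dens_mat / mrna_mat

  zero_single <- vapply(genes, function(g) {
    any(vapply(rna_pairs, function(p) rna_n[g, p$single] == 0, logical(1))) ||
      any(vapply(fp_pairs, function(p) fp_n[g, p$single] == 0, logical(1)))
  }, logical(1))

  out <- data.frame(gene = genes,
                    mrna_fold = rowMeans(mrna_mat),
                    te_fold = rowMeans(te_mat),
                    flagged = zero_single,
                    row.names = NULL)
  out$mrna_fold[zero_single] <- NA_real_
  out$te_fold[zero_single] <- NA_real_
  out
}

#' Build count matrices from read-level tables
#'
#' Counts reads per gene and sample with [count_gene()], producing the
#' matrices [te_fold_change()] consumes.
#'
#' @param reads data.frame with columns `transcript_id`, `five_prime`,
#'   `length`, `read_class`, `sample`.
#' @param cds data.frame with columns `transcript_id`, `cds_start`,
#'   `cds_end` (0-based half-open).
#' @param offset_table optional footprint offset override.
#' @return list of two genes x samples matrices: `footprint`,
#'   `mrna_fragment`.
#' @export
count_matrix <- function(reads, cds, offset_table = NULL) {
  samples <- sort(unique(reads$sample))
  genes <- cds$transcript_id
  mats <- lapply(c("footprint", "mrna_fragment"), function(cls) {
    m <- matrix(0L, nrow = length(genes), ncol = length(samples),
                dimnames = list(genes, samples))
    sub <- reads[reads$read_class == cls, , drop = FALSE]
    for (s in samples) {
      rs <- sub[sub$sample == s, , drop = FALSE]
      for (i in seq_along(genes))
        m[i, s] <- count_gene(rs, cds[i, ], offset_table)
    }
    m
  })
  names(mats) <- c("footprint", "mrna_fragment")
  mats
}
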