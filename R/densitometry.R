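#' Background-subtracted band intensity
#'
#' Densitometry quantifies each band as raw signal minus a locally measured
#' background; a background larger than the raw signal indicates a mis-drawn
#' background region and is an error, not a value to clip.
#'
#' @param raw raw band intensity (arbitrary units, >= 0).
#' @param background local background intensity (arbitrary units, >= 0).
#' @return net intensity, `raw - background`.
#' @examples
#' net_intensity(100, 20)
#' @export
net_intensity <- function(raw, background) {
  if (any(raw < 0)) stopf("raw intensity must be >= 0")
  if (any(background < 0)) stopf("background must be >= 0")
  if (any(background > raw))
    stopf("background exceeds raw intensity: invalid background region")
  raw - background
}

#' Dilution-series linearity check
#'
#' Fits net intensity against loaded amount by ordinary least squares and
#' reports the squared Pearson correlation. A quantification channel is in
#' its linear range when R^2 meets the threshold and no band is saturated.
#' Zero variance in the net intensities (the fully saturated case) is
#' defined as R^2 = 0 and fails the flag.
#'
#' @param dilutions strictly ordered positive dilution fractions (>= 3).
#' @param nets net intensities, same length.
#' @param saturated logical flags per band (default all `FALSE`).
#' @param threshold minimum R^2 for the linear-range flag (default 0.95).
#' @return list with `r_squared` and `in_linear_range`.
#' @examples
#' linearity_check(c(1, 1/2, 1/4), c(400, 200, 100))
#' @export
linearity_check <- function(dilutions, nets, saturated = FALSE,
                            threshold = 0.95) {
  if (length(dilutions) < 3L) stopf("linearity check needs >= 3 points")
  if (length(nets) != length(dilutions))
    stopf("dilutions and nets must have equal length")
  if (is.unsorted(dilutions) && is.unsorted(rev(dilutions)))
    stopf("dilutions must be strictly ordered")
  if (any(diff(dilutions) == 0)) stopf("dilutions must be strictly ordered")
  saturated <- rep_len(saturated, length(nets))
  r2 <- if (stats::sd(nets) == 0) 0 else stats::cor(dilutions, nets)^2
  list(r_squared = r2,
       in_linear_range = r2 >= threshold && !any(saturated))
}

#' Protein fold change from Western blot and loading-control intensities
#'
#' The Multi/Single ratio of the target band (WB fold change) divided by the
#' Multi/Single ratio of the loading-control band (PAGE fold change), which
#' cancels loading and exposure differences between lanes.
#'
#' @param target_single,target_multi net target-band intensities (> 0).
#' @param loading_single,loading_multi net loading-control intensities (> 0).
#' @param saturated logical flags for the four bands, in the argument order;
#'   any saturated band aborts the computation because saturated signal is
#'   not proportional to protein amount.
#' @return dimensionless fold change (Multi relative to Single).
#' @examples
#' protein_fold_change(100, 50, 100, 100) # target halved, loading equal
#' @export
protein_fold_change <- function(target_single, target_multi,
                                loading_single, loading_multi,
                                saturated = c(FALSE, FALSE, FALSE, FALSE)) {
  vals <- c(target_single, target_multi, loading_single, loading_multi)
  if (any(vals <= 0)) stopf("all net intensities must be > 0")
  if (any(saturated)) stopf("saturated band in fold-change computation; only non-saturated signals are usable")
  (target_multi / target_single) / (loading_multi / loading_single)
}

#' Fold change per gene copy
#'
#' Divides a total fold change (tagged protein from genome plus plasmid) by
#' the plasmid-borne copy number, giving the expression change per gene copy.
#' A per-copy fold near 1 means proportional (uncompensated) expression; a
#' value well below 1 is the compensation signature. The Single condition has
#' exactly one gene copy.
#'
#' @param fc_total total fold change (>= 0).
#' @param copies_multi gene copy number in the Multi condition (>= 1).
#' @return per-copy fold change.
#' @examples
#' per_copy_fold_change(10, 20)
#' @export
per_copy_fold_change <- function(fc_total, copies_multi) {
  check_number(fc_total, "fc_total", min = 0)
  check_number(copies_multi, "copies_multi", min = 1)
  fc_total / copies_multi
}

#' Ubiquitination level of an immunoprecipitated protein
#'
#' Normalizes the polyubiquitin smear intensity by the amount of
#' immunoprecipitated target protein loaded in the same lane.
#'
#' @param ub_smear net intensity of the ubiquitin smear (>= 0).
#' @param ip_loading net intensity of the immunoprecipitated target (> 0).
#' @return dimensionless ubiquitination level.
#' @export
ubiquitination_level <- function(ub_smear, ip_loading) {
  check_number(ub_smear, "ub_smear", min = 0)
  check_number(ip_loading, "ip_loading", min = 0, strict_min = TRUE)
  ub_smear / ip_loading
}

#' Cycloheximide-chase decay series
#'
#' Converts a CHX-chase time course into relative protein levels. Each
#' target intensity is normalized by the loading control (the 50-kDa band
#' corresponding to enolase) in the same lane, then expressed relative to
#' time 0. The half-life is estimated by ordinary least squares on
#' log relative level versus time: t1/2 = ln(2)/|slope|; a non-negative
#' slope (no decay) leaves the half-life undefined (`NA`).
#'
#' @param times sampling times in hours, starting at 0, strictly increasing.
#' @param target_nets net target intensities (> 0), one per time point.
#' @param loading_nets net loading-control intensities (> 0).
#' @return object of class `decay_series`: list with `times`,
#'   `relative_levels` (first element 1) and `half_life` (hours or `NA`).
#' @examples
#' chx_series(c(0, 1, 2, 4), 100 * 2^(-c(0, 1, 2, 4) / 2), rep(100, 4))
#' @export
chx_series <- function(times, target_nets, loading_nets) {
  if (length(times) != length(target_nets) ||
      length(times) != length(loading_nets))
    stopf("times, target_nets and loading_nets must have equal length")
  if (times[1] != 0) stopf("time course must start at time 0")
  if (any(diff(times) <= 0)) stopf("times must be strictly increasing")
  if (any(target_nets <= 0) || any(loading_nets <= 0))
    stopf("net intensities must be > 0")
  norm <- target_nets / loading_nets
  rel <- norm / norm[1]
  structure(list(times = times, relative_levels = rel,
                 half_life = fit_half_life(times, rel)),
            class = "decay_series")
}

# log-linear OLS half-life; refuses < 3 time points, NA when not decaying
fit_half_life <- function(times, relative_levels) {
  if (length(times) < 3L) stopf("half-life fit needs >= 3 time points")
  slope <- stats::coef(stats::lm(log(relative_levels) ~ times))[[2]]
  if (slope >= 0) NA_real_ else log(2) / abs(slope)
}

#' @export
print.decay_series <- function(x, ...) {
  cat("CHX decay series:", length(x$times), "time points\n")
  cat("  relative levels:",
      paste(sprintf("%.3f", x$relative_levels), collapse = ", "), "\n")
  cat("  half-life:",
      if (is.na(x$half_life)) "undefined (no decay)"
      else sprintf("%.3g h", x$half_life), "\n")
  invisible(x)
}

#' Quantify a band-intensity table into fold-change statistics
#'
#' Table-level driver for the Single/Multi blot quantification. For every
#' gene (`sample_id`) and replicate, the target and loading bands of both
#' conditions at the same dilution are combined with
#' [protein_fold_change()]; per-replicate folds are averaged across
#' dilutions, then aggregated across replicates as mean and sample standard
#' deviation. When copy numbers are supplied, per-copy fold changes are
#' computed per replicate before aggregation.
#'
#' @param bands data.frame with columns `sample_id`, `lane_id`, `band_role`
#'   (`target`/`loading`), `condition` (`single`/`multi`), `replicate`,
#'   `raw_intensity`, `background`, `dilution`, `saturated`.
#' @param copies optional data.frame with columns `sample_id`, `copies`.
#' @return data.frame of fold-change rows: `gene`, `kind`, `mean`, `sd`, `n`.
#' @export
quantify_bands <- function(bands, copies = NULL) {
  req <- c("sample_id", "band_role", "condition", "replicate",
           "raw_intensity", "background", "dilution", "saturated")
  missing <- setdiff(req, names(bands))
  if (length(missing))
    stopf("bands table is missing column(s): %s", paste(missing, collapse = ", "))
  key <- bands[bands$band_role %in% c("target", "loading"), , drop = FALSE]
  dup <- duplicated(key[c("sample_id", "lane_id", "band_role")])
  if (any(dup)) stopf("duplicate (sample_id, lane_id, band_role) in bands table")
  bands$net <- net_intensity(bands$raw_intensity, bands$background)
  bands$saturated <- as.logical(bands$saturated)

  out <- list()
  for (gene in unique(bands$sample_id)) {
    g <- bands[bands$sample_id == gene, , drop = FALSE]
    rep_folds <- vapply(sort(unique(g$replicate)), function(r) {
      gr <- g[g$replicate == r, , drop = FALSE]
      folds <- vapply(unique(gr$dilution), function(d) {
        grd <- gr[gr$dilution == d, , drop = FALSE]
        pick <- function(role, cond) {
          row <- grd[grd$band_role == role & grd$condition == cond, , drop = FALSE]
          if (nrow(row) != 1L)
            stopf("gene %s replicate %s dilution %g: need exactly one %s/%s band",
                  gene, r, d, role, cond)
          row
        }
        ts <- pick("target", "single"); tm <- pick("target", "multi")
        ls <- pick("loading", "single"); lm_ <- pick("loading", "multi")
        protein_fold_change(ts$net, tm$net, ls$net, lm_$net,
                            saturated = c(ts$saturated, tm$saturated,
                                          ls$saturated, lm_$saturated))
      }, numeric(1))
      mean(folds)
    }, numeric(1))

    agg <- aggregate_replicates(rep_folds)
    out[[length(out) + 1L]] <- data.frame(
      gene = gene, kind = "protein",
      mean = agg$mean, sd = agg$sd, n = agg$n)

    if (!is.null(copies)) {
      ci <- copies$copies[match(gene, copies$sample_id)]
      if (!is.na(ci)) {
        pc <- vapply(rep_folds, per_copy_fold_change, numeric(1),
                     copies_multi = ci)
        agg <- aggregate_replicates(pc)
        out[[length(out) + 1L]] <- data.frame(
          gene = gene, kind = "protein_per_copy",
          mean = agg$mean, sd = agg$sd, n = agg$n)
      }
    }
  }
  do.call(rbind, out)
}
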