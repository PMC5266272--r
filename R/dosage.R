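#' Plasmid copy number from gTOW qPCR
#'
#' Efficiency-corrected relative quantification of the plasmid marker
#' (`leu2d`) against the single-copy genomic reference locus (`LEU3`):
#' copies = eff_leu3^Cp_LEU3 / eff_leu2d^Cp_leu2d, which reduces to
#' 2^(Cp_LEU3 - Cp_leu2d) when both primer efficiencies are the ideal 2.
#' A leu2d crossing point one cycle earlier than LEU3 therefore means two
#' plasmid copies per genome.
#'
#' @param cp_leu2d crossing point of the plasmid marker (cycles, > 0).
#' @param cp_leu3 crossing point of the genomic reference (cycles, > 0).
#' @param eff_leu2d,eff_leu3 per-cycle amplification factors in (1, 2].
#' @return estimated plasmid copies per cell.
#' @examples
#' plasmid_copy_number(18, 18)        # 1 copy
#' plasmid_copy_number(17, 18)        # one cycle earlier: 2 copies
#' @export
plasmid_copy_number <- function(cp_leu2d, cp_leu3,
                                eff_leu2d = 2, eff_leu3 = 2) {
  if (missing(cp_leu2d) || missing(cp_leu3) ||
      is.na(cp_leu2d) || is.na(cp_leu3))
    stopf("both leu2d and LEU3 crossing points are required")
  check_number(cp_leu2d, "cp_leu2d", min = 0, strict_min = TRUE)
  check_number(cp_leu3, "cp_leu3", min = 0, strict_min = TRUE)
  for (e in c(eff_leu2d, eff_leu3))
    if (e <= 1 || e > 2) stopf("primer efficiency must be in (1, 2]")
  eff_leu3^cp_leu3 / eff_leu2d^cp_leu2d
}

#' mRNA fold change by relative quantification (delta-delta-Cp)
#'
#' Fold change of a target transcript between the Multi and Single
#' conditions, normalized to a reference transcript (ACT1):
#' fold = 2^-((Cp_t,multi - Cp_r,multi) - (Cp_t,single - Cp_r,single)) at the
#' default efficiency 2, generalized to per-primer efficiencies as
#' eff_t^(Cp_t,single - Cp_t,multi) / eff_r^(Cp_r,single - Cp_r,multi).
#'
#' @param cp_target_multi,cp_ref_multi crossing points in the Multi condition.
#' @param cp_target_single,cp_ref_single crossing points in the Single
#'   condition.
#' @param eff_target,eff_ref per-cycle amplification factors in (1, 2].
#' @return dimensionless mRNA fold change (Multi relative to Single).
#' @examples
#' mrna_fold_change(19, 20, 20, 20) # target one cycle earlier in Multi: 2
#' @export
mrna_fold_change <- function(cp_target_multi, cp_ref_multi,
                             cp_target_single, cp_ref_single,
                             eff_target = 2, eff_ref = 2) {
  cps <- c(cp_target_multi, cp_ref_multi, cp_target_single, cp_ref_single)
  if (length(cps) != 4L || any(is.na(cps)))
    stopf("all four crossing points are required")
  for (e in c(eff_target, eff_ref))
    if (e <= 1 || e > 2) stopf("primer efficiency must be in (1, 2]")
  eff_target^(cp_target_single - cp_target_multi) /
    eff_ref^(cp_ref_single - cp_ref_multi)
}

#' Copy-number estimates from a Cp table
#'
#' Computes per-replicate plasmid copy numbers with [plasmid_copy_number()]
#' and aggregates them as mean and sample standard deviation per sample.
#'
#' @param cp data.frame with columns `sample_id`, `primer_target`
#'   (`leu2d`/`LEU3`), `cp`, `replicate` and optionally `efficiency`.
#' @return data.frame with `sample_id`, `copies`, `sd`, `n`.
#' @export
estimate_copy_numbers <- function(cp) {
  req <- c("sample_id", "primer_target", "cp", "replicate")
  missing <- setdiff(req, names(cp))
  if (length(missing))
    stopf("Cp table is missing column(s): %s", paste(missing, collapse = ", "))
  if (is.null(cp$efficiency)) cp$efficiency <- 2
  out <- lapply(unique(cp$sample_id), function(s) {
    cs <- cp[cp$sample_id == s, , drop = FALSE]
    est <- vapply(sort(unique(cs$replicate)), function(r) {
      cr <- cs[cs$replicate == r, , drop = FALSE]
      ld <- cr[cr$primer_target == "leu2d", , drop = FALSE]
      l3 <- cr[cr$primer_target == "LEU3", , drop = FALSE]
      if (nrow(ld) != 1L || nrow(l3) != 1L)
        stopf("sample %s replicate %s: need one leu2d and one LEU3 Cp", s, r)
      plasmid_copy_number(ld$cp, l3$cp, ld$efficiency, l3$efficiency)
    }, numeric(1))
    agg <- aggregate_replicates(est)
    data.frame(sample_id = s, copies = agg$mean, sd = agg$sd, n = agg$n)
  })
  do.call(rbind, out)
}

#' mRNA fold changes from an RT-qPCR Cp table
#'
#' Pairs target (`TAP`) and reference (`ACT1`) crossing points of the Single
#' and Multi conditions per replicate and aggregates the per-replicate
#' [mrna_fold_change()] values.
#'
#' @param cp data.frame with columns `sample_id`, `primer_target`
#'   (`TAP`/`ACT1`), `cp`, `replicate`, `condition` (`single`/`multi`) and
#'   optionally `efficiency`.
#' @return data.frame of fold-change rows: `gene`, `kind` (`mrna`), `mean`,
#'   `sd`, `n`.
#' @export
estimate_mrna_folds <- function(cp) {
  req <- c("sample_id", "primer_target", "cp", "replicate", "condition")
  missing <- setdiff(req, names(cp))
  if (length(missing))
    stopf("Cp table is missing column(s): %s", paste(missing, collapse = ", "))
  if (is.null(cp$efficiency)) cp$efficiency <- 2
  out <- lapply(unique(cp$sample_id), function(s) {
    cs <- cp[cp$sample_id == s, , drop = FALSE]
    folds <- vapply(sort(unique(cs$replicate)), function(r) {
      cr <- cs[cs$replicate == r, , drop = FALSE]
      pick <- function(target, cond) {
        row <- cr[cr$primer_target == target & cr$condition == cond, , drop = FALSE]
        if (nrow(row) != 1L)
          stopf("sample %s replicate %s: need one %s Cp in condition %s",
                s, r, target, cond)
        row
      }
      tm <- pick("TAP", "multi"); rm_ <- pick("ACT1", "multi")
      ts <- pick("TAP", "single"); rs <- pick("ACT1", "single")
      mrna_fold_change(tm$cp, rm_$cp, ts$cp, rs$cp,
                       eff_target = tm$efficiency, eff_ref = rm_$efficiency)
    }, numeric(1))
    agg <- aggregate_replicates(folds)
    data.frame(gene = s, kind = "mrna", mean = agg$mean, sd = agg$sd, n = agg$n)
  })
  do.call(rbind, out)
}
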