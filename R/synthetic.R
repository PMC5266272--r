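# Seeded generators for every input the pipeline consumes. Each returns the
# generated table(s) together with `truth`, the programmed parameters, so
# every analysis stage can be round-trip tested without external data.
# Identical seed and arguments give identical output.

#' Synthetic Western-blot band table
#'
#' Emulates a Single/Multi quantification blot with a dilution series:
#' band intensity = background + gain x level x dilution x lane factor x
#' multiplicative lognormal noise, clipped and flagged at the saturation
#' ceiling. The loading-control level is condition-independent; a common
#' lane factor on both bands of a lane emulates loading/exposure variation
#' and cancels in the fold-change computation.
#'
#' @param true_fold programmed Multi/Single protein fold change.
#' @param n_replicates biological replicates.
#' @param dilution_series dilution fractions per lane (default 1).
#' @param background_mean local background level (AU).
#' @param noise_cv per-band multiplicative noise CV (>= 0).
#' @param lane_cv per-lane loading-variation CV (>= 0).
#' @param saturation_ceiling intensity ceiling (AU); bands at the ceiling
#'   are flagged saturated.
#' @param gain detector gain (AU per level unit).
#' @param sample_id gene/sample label.
#' @param seed integer seed.
#' @return list with `bands` (a band-measurement data.frame) and `truth`.
#' @examples
#' b <- gen_blot(true_fold = 0.3, seed = 1)
#' quantify_bands(b$bands)
#' @export
gen_blot <- function(true_fold = 0.3, n_replicates = 3, dilution_series = 1,
                     background_mean = 20, noise_cv = 0.03, lane_cv = 0.05,
                     saturation_ceiling = Inf, gain = 1000,
                     sample_id = "gene1", seed = 1) {
  if (true_fold <= 0) stopf("true_fold must be > 0")
  if (noise_cv < 0 || lane_cv < 0) stopf("noise CV must be >= 0")
  levels <- c(single = 1, multi = true_fold)
  withr::with_seed(seed, {
    rows <- list()
    for (r in seq_len(n_replicates)) for (cond in names(levels)) {
      for (d in dilution_series) {
        lane <- sprintf("%s_r%d_d%g", cond, r, d)
        lane_f <- rlnorm_cv(1, lane_cv)
        for (role in c("target", "loading")) {
          lev <- if (role == "target") levels[[cond]] else 1
          sig <- gain * lev * d * lane_f * rlnorm_cv(1, noise_cv)
          raw <- background_mean + sig
          sat <- raw >= saturation_ceiling
          rows[[length(rows) + 1L]] <- data.frame(
            sample_id = sample_id, lane_id = paste0(lane, "_", role),
            band_role = role, condition = cond, replicate = r,
            raw_intensity = min(raw, saturation_ceiling),
            background = background_mean, dilution = d, saturated = sat)
        }
      }
    }
    list(bands = do.call(rbind, rows),
         truth = list(fold = true_fold, noise_cv = noise_cv,
                      lane_cv = lane_cv, gain = gain,
                      background_mean = background_mean))
  })
}

#' Synthetic qPCR crossing-point table
#'
#' Emulates gTOW copy-number qPCR (leu2d vs the single-copy LEU3 locus)
#' and/or RT-qPCR mRNA quantification (TAP vs ACT1, Single and Multi
#' conditions). Ideal crossing points follow the efficiency model
#' (one abundance doubling per cycle at efficiency 2) with additive normal
#' noise of standard deviation `cp_noise_sd`.
#'
#' @param true_copies programmed plasmid copies/cell, or `NULL` to skip the
#'   gTOW records.
#' @param true_mrna_fold programmed mRNA Multi/Single fold, or `NULL` to
#'   skip the RT records.
#' @param efficiency per-cycle amplification factor in (1, 2].
#' @param cp_noise_sd additive Cp noise standard deviation (cycles).
#' @param n_replicates biological replicates.
#' @param sample_id sample label.
#' @param seed integer seed.
#' @return list with `cp` (a Cp-record data.frame) and `truth`.
#' @examples
#' q <- gen_qpcr(true_copies = 20, seed = 1)
#' estimate_copy_numbers(q$cp)
#' @export
gen_qpcr <- function(true_copies = NULL, true_mrna_fold = NULL,
                     efficiency = 2, cp_noise_sd = 0.1, n_replicates = 4,
                     sample_id = "gene1", seed = 1) {
  if (is.null(true_copies) && is.null(true_mrna_fold))
    stopf("specify true_copies and/or true_mrna_fold")
  if (cp_noise_sd < 0) stopf("cp_noise_sd must be >= 0")
  if (efficiency <= 1 || efficiency > 2)
    stopf("efficiency must be in (1, 2]")
  withr::with_seed(seed, {
    rows <- list()
    add <- function(target, cp0, r, cond) {
      rows[[length(rows) + 1L]] <<- data.frame(
        sample_id = sample_id, primer_target = target,
        cp = cp0 + stats::rnorm(1, 0, cp_noise_sd),
        efficiency = efficiency, replicate = r, condition = cond)
    }
    for (r in seq_len(n_replicates)) {
      if (!is.null(true_copies)) {
        cp_leu3 <- 18
        cp_leu2d <- cp_leu3 - log(true_copies) / log(efficiency)
        add("LEU3", cp_leu3, r, "multi")
        add("leu2d", cp_leu2d, r, "multi")
      }
      if (!is.null(true_mrna_fold)) {
        add("ACT1", 20, r, "single")
        add("TAP", 23, r, "single")
        add("ACT1", 20, r, "multi")
        add("TAP", 23 - log(true_mrna_fold) / log(efficiency), r, "multi")
      }
    }
    list(cp = do.call(rbind, rows),
         truth = list(copies = true_copies, mrna_fold = true_mrna_fold,
                      efficiency = efficiency, cp_noise_sd = cp_noise_sd))
  })
}

#' Synthetic dosage-compensation screen
#'
#' Emulates a chromosome-scale screen: `n_compensated` genes draw
#' per-replicate protein folds from a low-median lognormal (compensation
#' by degradation of the excess), the rest sit near fold 1; endogenous mRNA
#' folds are near 1 for both groups (the compensation is
#' post-transcriptional). Compensated genes are assigned complex
#' memberships.
#'
#' @param n_genes genes screened.
#' @param n_compensated programmed compensated genes.
#' @param n_replicates replicates per gene.
#' @param comp_median,uncomp_median median protein fold of each group.
#' @param comp_cv,uncomp_cv lognormal CV of protein folds.
#' @param mrna_cv lognormal CV of mRNA folds (median 1).
#' @param seed integer seed.
#' @return list with `folds` (long table: gene, complex_id, kind, fold,
#'   replicate), `complexes`, and `truth` (per-gene labels).
#' @examples
#' s <- gen_screen(seed = 1)
#' table(classify_screen(s$folds)$classification)
#' @export
gen_screen <- function(n_genes = 54, n_compensated = 5, n_replicates = 3,
                       comp_median = 0.4, comp_cv = 0.2,
                       uncomp_median = 1.0, uncomp_cv = 0.15,
                       mrna_cv = 0.15, seed = 1) {
  if (n_compensated > n_genes) stopf("n_compensated cannot exceed n_genes")
  genes <- sprintf("gene%02d", seq_len(n_genes))
  comp <- seq_len(n_genes) <= n_compensated
  complex_id <- ifelse(comp, sprintf("cpx%d", seq_len(n_genes)), NA_character_)
  withr::with_seed(seed, {
    rows <- list()
    for (i in seq_len(n_genes)) {
      med <- if (comp[i]) comp_median else uncomp_median
      cv <- if (comp[i]) comp_cv else uncomp_cv
      pf <- med * rlnorm_cv(n_replicates, cv)
      mf <- rlnorm_cv(n_replicates, mrna_cv)
      rows[[length(rows) + 1L]] <- data.frame(
        gene = genes[i], complex_id = complex_id[i],
        kind = rep(c("protein", "mrna"), each = n_replicates),
        fold = c(pf, mf), replicate = rep(seq_len(n_replicates), 2))
    }
    complexes <- data.frame(
      complex_id = complex_id[comp],
      n_subunits = rep(2L, sum(comp)))
    list(folds = do.call(rbind, rows),
         complexes = complexes,
         truth = data.frame(gene = genes, compensated = comp,
                            complex_id = complex_id))
  })
}

#' Synthetic ribosome-profiling and RNA-seq counts
#'
#' Emulates a Single/Multi profiling experiment: negative-binomial counts
#' with mean proportional to library size x mRNA level (x TE for
#' footprints). One designated gene can carry a programmed perturbation
#' pattern, e.g. mRNA x20 with unchanged TE -- the signature of a gene
#' whose copy number rose but whose compensation is not translational.
#' In read-level mode the same counts are realized as individual reads with
#' footprint lengths drawn from 26--30 nt and A-sites placed uniformly in
#' the countable CDS window, so matrix- and read-level paths share one
#' truth.
#'
#' @param n_genes background genes (programmed fold 1).
#' @param target_gene name of the designated perturbed gene.
#' @param target_mrna_fold programmed Multi/Single mRNA fold of the target.
#' @param target_te_fold programmed TE fold of the target.
#' @param n_replicates replicate pairs.
#' @param base_mean mean Single-condition count per gene.
#' @param library_sizes per-sample depth multipliers, length
#'   `2 * n_replicates` (single then multi per replicate), default all 1.
#' @param dispersion negative-binomial dispersion (0 = Poisson).
#' @param cds_length CDS length nt (multiple of 3, >= 63).
#' @param read_level also emit a read-level table realizing the counts.
#' @param seed integer seed.
#' @return list with `counts` (matrices `footprint`, `mrna_fragment`),
#'   `design`, `cds`, `reads` (`NULL` unless `read_level`), and `truth`.
#' @examples
#' r <- gen_ribo(seed = 1)
#' te <- te_fold_change(r$counts$footprint, r$counts$mrna_fragment, r$design)
#' te[te$gene == "POP5like", ]
#' @export
gen_ribo <- function(n_genes = 30, target_gene = "POP5like",
                     target_mrna_fold = 20, target_te_fold = 1,
                     n_replicates = 2, base_mean = 500,
                     library_sizes = NULL, dispersion = 0.01,
                     cds_length = 900, read_level = FALSE, seed = 1) {
  if (dispersion < 0) stopf("dispersion must be >= 0")
  genes <- c(target_gene, sprintf("bg%02d", seq_len(n_genes)))
  mrna_fold <- c(target_mrna_fold, rep(1, n_genes))
  te_fold <- c(target_te_fold, rep(1, n_genes))
  samples <- as.vector(vapply(seq_len(n_replicates), function(r)
    c(sprintf("single_r%d", r), sprintf("multi_r%d", r)), character(2)))
  cond <- rep(c("single", "multi"), n_replicates)
  if (is.null(library_sizes)) library_sizes <- rep(1, length(samples))
  if (length(library_sizes) != length(samples))
    stopf("library_sizes must have length %d", length(samples))
  design <- data.frame(sample = samples, condition = cond,
                       replicate = rep(seq_len(n_replicates), each = 2))
  cds <- data.frame(transcript_id = genes, cds_start = 60L,
                    cds_end = 60L + as.integer(cds_length))

  withr::with_seed(seed, {
    draw <- function(mu) {
      if (dispersion == 0) stats::rpois(length(mu), mu)
      else stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion)
    }
    mk <- function(with_te) {
      m <- matrix(0L, length(genes), length(samples),
                  dimnames = list(genes, samples))
      for (j in seq_along(samples)) {
        lev <- if (cond[j] == "multi") mrna_fold else rep(1, length(genes))
        te <- if (with_te && cond[j] == "multi") te_fold else rep(1, length(genes))
        m[, j] <- as.integer(draw(base_mean * library_sizes[j] * lev * te))
      }
      m
    }
    counts <- list(footprint = mk(TRUE), mrna_fragment = mk(FALSE))
    reads <- NULL
    if (read_level) {
      win_s <- cds$cds_start[1] + 45L
      win_e <- cds$cds_end[1] - 15L
      place <- function(n, g, s, cls) {
        if (n == 0) return(NULL)
        asite <- sample(win_s:(win_e - 1L), n, replace = TRUE)
        len <- if (cls == "footprint") sample(26:30, n, replace = TRUE)
               else sample(22:51, n, replace = TRUE)
        off <- ifelse(rep(cls == "footprint", n), len - 13L, 15L)
        data.frame(transcript_id = g, five_prime = asite - off,
                   length = len, read_class = cls, sample = s)
      }
      parts <- list()
      for (cls in names(counts)) for (s in samples) for (g in genes)
        parts[[length(parts) + 1L]] <- place(counts[[cls]][g, s], g, s, cls)
      reads <- do.call(rbind, parts)
    }
    list(counts = counts, design = design, cds = cds, reads = reads,
         truth = data.frame(gene = genes, mrna_fold = mrna_fold,
                            te_fold = te_fold))
  })
}

#' Synthetic cycloheximide-chase time course
#'
#' Exponential decay of the target band at the programmed half-life, a
#' constant loading control, both with multiplicative lognormal noise.
#' An infinite half-life gives a flat series.
#'
#' @param half_life programmed half-life in hours (`Inf` for no decay).
#' @param times sampling times in hours starting at 0.
#' @param noise_cv multiplicative noise CV.
#' @param target0,loading_level time-0 band levels (AU).
#' @param sample_id sample label.
#' @param seed integer seed.
#' @return list with `series` (data.frame: sample_id, time_h, target_net,
#'   loading_net) and `truth`.
#' @examples
#' x <- gen_chx(half_life = 1.5, seed = 1)
#' chx_series(x$series$time_h, x$series$target_net, x$series$loading_net)
#' @export
gen_chx <- function(half_life = 1.5, times = c(0, 1, 2, 4, 6),
                    noise_cv = 0.05, target0 = 1000, loading_level = 1000,
                    sample_id = "gene1", seed = 1) {
  if (half_life <= 0) stopf("half_life must be > 0")
  withr::with_seed(seed, {
    decay <- if (is.infinite(half_life)) rep(1, length(times))
             else 2^(-times / half_life)
    series <- data.frame(
      sample_id = sample_id, time_h = times,
      target_net = target0 * decay * rlnorm_cv(length(times), noise_cv),
      loading_net = loading_level * rlnorm_cv(length(times), noise_cv))
    list(series = series,
         truth = list(half_life = half_life, noise_cv = noise_cv))
  })
}
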