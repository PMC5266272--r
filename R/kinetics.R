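#' Two-pool heterodimer assembly--degradation model
#'
#' Mass-action model of a heterodimer A-B in which each subunit exists in
#' two pools: an unstable free-monomer pool degraded at `d_free_*`, and a
#' stable complex-bound pool degraded at `d_complex`. Synthesis is
#' proportional to gene copy number, association is bimolecular:
#'
#' \deqn{dA/dt = N_A s_A - d_{free,A} A - k_{on} A B + k_{off} C}
#' \deqn{dB/dt = N_B s_B - d_{free,B} B - k_{on} A B + k_{off} C}
#' \deqn{dC/dt = k_{on} A B - k_{off} C - d_{complex} C}
#'
#' `d_free >= d_complex` encodes that a monomer is stabilized by complex
#' formation; with that asymmetry, increasing the gene dosage of one subunit
#' enlarges its unstable pool and its total level rises sub-proportionally
#' (dosage compensation), while extra partner dosage stabilizes it.
#'
#' Tagged-species bookkeeping exploits that tagged and untagged chains are
#' kinetically identical: the tagged share of every pool equals
#' `tagged_copies_A / N_A`, so no separate tagged equations are integrated.
#'
#' @param s_A,s_B synthesis rate per gene copy (AU/time, >= 0).
#' @param N_A,N_B gene copy numbers (>= 0).
#' @param d_free_A,d_free_B free-monomer degradation rates (1/time, >= 0).
#' @param d_complex complex degradation rate (1/time, >= 0).
#' @param k_on association rate (1/(AU time), >= 0).
#' @param k_off dissociation rate (1/time, >= 0; 0 models a tight dimer).
#' @param tagged_copies_A number of tagged A gene copies (0 <= value <= N_A;
#'   default 1, the genomic tagged copy).
#' @return object of class `heterodimer_model`.
#' @examples
#' m <- heterodimer_model(s_A = 1.5, s_B = 1, d_free_A = 5, d_free_B = 5,
#'                        d_complex = 1, k_on = 100)
#' steady_state(m)
#' @export
heterodimer_model <- function(s_A, s_B, d_free_A, d_free_B, d_complex, k_on,
                              N_A = 1, N_B = 1, k_off = 0,
                              tagged_copies_A = 1) {
  m <- list(s_A = s_A, s_B = s_B, N_A = N_A, N_B = N_B,
            d_free_A = d_free_A, d_free_B = d_free_B,
            d_complex = d_complex, k_on = k_on, k_off = k_off,
            tagged_copies_A = tagged_copies_A)
  for (nm in names(m)) check_number(m[[nm]], nm, min = 0)
  if (tagged_copies_A > N_A)
    stopf("tagged_copies_A (%g) cannot exceed N_A (%g)", tagged_copies_A, N_A)
  structure(m, class = "heterodimer_model")
}

#' Read a heterodimer model from a YAML configuration file
#'
#' Keys are exactly the [heterodimer_model()] field names; unknown keys are
#' rejected.
#'
#' @param path YAML file path.
#' @return a `heterodimer_model`.
#' @export
read_model <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- names(formals(heterodimer_model))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stopf("unknown model key(s) in '%s': %s", path,
          paste(unknown, collapse = ", "))
  do.call(heterodimer_model, cfg)
}

#' The shipped default model calibration
#'
#' Loads the package's default parameter set (`extdata/default_model.yaml`):
#' s_A = 1.5, s_B = 1.0, d_free = 5.0, d_complex = 1.0, k_on = 100,
#' k_off = 0, single gene copies, one tagged A copy. This calibration places
#' the model's perturbation predictions inside the experimentally observed
#' ranges (multicopy-self fold in 0.2--0.6, partner-deletion fold below 0.5,
#' multicopy-partner fold above 1.3).
#'
#' @return a `heterodimer_model`.
#' @export
default_model <- function() {
  read_model(system.file("extdata", "default_model.yaml",
                         package = "stoichbuffer", mustWork = TRUE))
}

#' @export
print.heterodimer_model <- function(x, ...) {
  cat("Heterodimer two-pool model\n")
  cat(sprintf("  synthesis: s_A=%g x N_A=%g, s_B=%g x N_B=%g\n",
              x$s_A, x$N_A, x$s_B, x$N_B))
  cat(sprintf("  degradation: d_free_A=%g, d_free_B=%g, d_complex=%g\n",
              x$d_free_A, x$d_free_B, x$d_complex))
  cat(sprintf("  binding: k_on=%g, k_off=%g; tagged A copies: %g\n",
              x$k_on, x$k_off, x$tagged_copies_A))
  invisible(x)
}

#' Steady state of the heterodimer model
#'
#' Solves the steady-state system in closed form. Net flux into the complex
#' pool at steady state is `kappa * A * B` with
#' `kappa = k_on * d_complex / (k_off + d_complex)`, so the free-monomer
#' balance reduces to one quadratic in the partner concentration for any
#' `k_off`. The returned state carries the tagged shares
#' `tagged_A_free = A_free * tagged_copies_A / N_A` (likewise `tagged_C`).
#' Residual fluxes are verified to 1e-9 in relative terms.
#'
#' @param model a [heterodimer_model()].
#' @return object of class `steady_state`: list with `A_free`, `B_free`,
#'   `C`, `tagged_A_free`, `tagged_C`.
#' @export
steady_state <- function(model) {
  stopifnot(inherits(model, "heterodimer_model"))
  P <- model$N_A * model$s_A
  Q <- model$N_B * model$s_B
  dfa <- model$d_free_A; dfb <- model$d_free_B
  dc <- model$d_complex; kon <- model$k_on; koff <- model$k_off

  if (P == 0 && Q == 0) return(make_state(0, 0, 0, model))

  if (kon > 0 && dc == 0 && koff == 0)
    stopf("no steady state: complex is formed (k_on > 0) but never degraded or dissociated")
  kappa <- if (kon == 0) 0 else kon * dc / (koff + dc)

  if (kappa == 0) {
    # no net flux through the complex: decoupled birth-death for monomers
    if ((P > 0 && dfa == 0) || (Q > 0 && dfb == 0))
      stopf("no steady state: synthesized monomer has zero degradation rate")
    A <- if (P > 0) P / dfa else 0
    B <- if (Q > 0) Q / dfb else 0
    C <- if (koff > 0) kon * A * B / koff else 0
    return(make_state(A, B, C, model))
  }

  if (dfa == 0 || dfb == 0)
    stopf("no steady state: free degradation rate is zero with active assembly")

  # quadratic in B: (kappa*dfb/dfa) B^2 + (kappa*(P-Q)/dfa + dfb) B - Q = 0
  aq <- kappa * dfb / dfa
  bq <- kappa * (P - Q) / dfa + dfb
  B <- if (Q == 0) 0 else 2 * Q / (bq + sqrt(bq^2 + 4 * aq * Q))
  A <- (P - Q + dfb * B) / dfa
  C <- kon * A * B / (koff + dc)

  st <- make_state(A, B, C, model)
  res <- steady_residuals(st, model)
  if (max(abs(res)) > 1e-9)
    stopf("steady-state solver failed: max relative residual %.3g", max(abs(res)))
  st
}

make_state <- function(A, B, C, model) {
  share <- if (model$N_A > 0) model$tagged_copies_A / model$N_A else 0
  structure(list(A_free = A, B_free = B, C = C,
                 tagged_A_free = A * share, tagged_C = C * share),
            class = "steady_state")
}

# relative residuals of the three balance equations
steady_residuals <- function(state, model) {
  A <- state$A_free; B <- state$B_free; C <- state$C
  fA <- model$N_A * model$s_A - model$d_free_A * A -
    model$k_on * A * B + model$k_off * C
  fB <- model$N_B * model$s_B - model$d_free_B * B -
    model$k_on * A * B + model$k_off * C
  fC <- model$k_on * A * B - (model$k_off + model$d_complex) * C
  scale <- max(model$N_A * model$s_A, model$N_B * model$s_B,
               model$k_on * A * B, 1e-300)
  c(fA, fB, fC) / scale
}

#' @export
print.steady_state <- function(x, ...) {
  cat(sprintf("Steady state: A_free=%.6g, B_free=%.6g, C=%.6g\n",
              x$A_free, x$B_free, x$C))
  cat(sprintf("  tagged: A_free=%.6g, C=%.6g, total=%.6g\n",
              x$tagged_A_free, x$tagged_C, x$tagged_A_free + x$tagged_C))
  invisible(x)
}

#' Apply a genetic or proteolytic perturbation to a model
#'
#' @param model a [heterodimer_model()].
#' @param kind one of `"multicopy_self"` (raise `N_A` to `value`),
#'   `"multicopy_partner"` (raise `N_B` to `value`), `"partner_deletion"`
#'   (zero the partner synthesis flux), `"proteasome_defect"` (scale the
#'   free-pool degradation rates toward the complex rate:
#'   `d_free <- d_complex + value * (d_free - d_complex)`, `value` in
#'   \[0, 1\]; 0 is a full defect collapsing the stability difference).
#' @param value perturbation magnitude where applicable (`N >= 1` for
#'   multicopy kinds, `f` in \[0, 1\] for the proteasome defect).
#' @return a perturbed `heterodimer_model` (tag bookkeeping preserved).
#' @examples
#' perturb(default_model(), "multicopy_self", 20)
#' @export
perturb <- function(model, kind, value = NULL) {
  stopifnot(inherits(model, "heterodimer_model"))
  switch(kind,
    multicopy_self = {
      check_number(value, "value", min = 1)
      model$N_A <- value
    },
    multicopy_partner = {
      check_number(value, "value", min = 1)
      model$N_B <- value
    },
    partner_deletion = {
      model$N_B <- 0
    },
    proteasome_defect = {
      check_number(value, "value", min = 0)
      if (value > 1) stopf("proteasome_defect factor must be in [0, 1]")
      model$d_free_A <- model$d_complex + value * (model$d_free_A - model$d_complex)
      model$d_free_B <- model$d_complex + value * (model$d_free_B - model$d_complex)
    },
    stopf("unknown perturbation kind: '%s'", kind)
  )
  model
}

observable_value <- function(state, observable) {
  switch(observable,
    tagged_total_A = state$tagged_A_free + state$tagged_C,
    tagged_complex = state$tagged_C,
    total_A = state$A_free + state$C,
    stopf("unknown observable: '%s'", observable))
}

#' Steady-state fold change of an observable under a perturbation
#'
#' Ratio of an observable at the perturbed steady state to its baseline
#' value. `tagged_total_A` (free plus complexed tagged subunit) is what a
#' denaturing blot of the tagged protein measures; `tagged_complex` is the
#' native-gel complex band; `total_A` ignores the tag.
#'
#' @param model baseline [heterodimer_model()].
#' @param kind,value perturbation as in [perturb()].
#' @param observable one of `"tagged_total_A"`, `"tagged_complex"`,
#'   `"total_A"`.
#' @return dimensionless fold change.
#' @examples
#' fold_change(default_model(), "multicopy_self", 20) # ~0.38: compensation
#' @export
fold_change <- function(model, kind, value = NULL,
                        observable = "tagged_total_A") {
  base <- observable_value(steady_state(model), observable)
  if (base == 0) stopf("baseline observable '%s' is zero", observable)
  pert <- observable_value(steady_state(perturb(model, kind, value)),
                           observable)
  pert / base
}

#' Simulate a cycloheximide chase from the model's steady state
#'
#' CHX blocks translation: both synthesis fluxes are set to zero and the
#' system is integrated from the steady state. The reported series is the
#' total tagged subunit (free + complexed) relative to time 0 -- the
#' observable of a chase blot.
#'
#' @param model a [heterodimer_model()] with a nonzero steady state.
#' @param times sampling times in hours starting at 0, strictly increasing.
#' @return a `decay_series` (see [chx_series()]); the half-life is fitted
#'   when at least three time points are given.
#' @examples
#' simulate_chx(default_model(), c(0, 1, 2, 4, 6))
#' @export
simulate_chx <- function(model, times) {
  stopifnot(inherits(model, "heterodimer_model"))
  if (times[1] != 0) stopf("chase time grid must start at 0")
  if (any(diff(times) <= 0)) stopf("times must be strictly increasing")
  st <- steady_state(model)
  y0 <- c(A = st$A_free, B = st$B_free, C = st$C)
  total0 <- st$A_free + st$C
  if (total0 <= 0) stopf("steady-state level of the tagged subunit is zero")
  deriv <- function(t, y, p) {
    list(c(
      A = -model$d_free_A * y["A"] - model$k_on * y["A"] * y["B"] +
        model$k_off * y["C"],
      B = -model$d_free_B * y["B"] - model$k_on * y["A"] * y["B"] +
        model$k_off * y["C"],
      C = model$k_on * y["A"] * y["B"] -
        (model$k_off + model$d_complex) * y["C"]))
  }
  sol <- deSolve::ode(y = y0, times = times, func = deriv, parms = NULL,
                      rtol = 1e-10, atol = 1e-12)
  if (!is.null(attr(sol, "istate")) && attr(sol, "istate")[1] < 0)
    stopf("CHX chase integration failed")
  rel <- (sol[, "A"] + sol[, "C"]) / total0
  structure(list(times = times, relative_levels = as.numeric(rel),
                 half_life = if (length(times) >= 3L)
                   fit_half_life(times, pmax(rel, 1e-300)) else NA_real_),
            class = "decay_series")
}

#' Closed-form fold change in the fast-association limit
#'
#' Analytic oracle for the limit `k_on -> Inf`, `k_off = 0` in the
#' partner-limited regime (`s_A >= s_B`): every partner molecule is captured
#' into complex, so complexes sit at `s_B / d_complex`, the leftover
#' `N * s_A - s_B` flux populates the unstable free pool, and the tagged
#' total fold at self copy number `N` is
#' \deqn{fold(N) = \frac{s_B/(N d_c) + (N s_A - s_B)/(N d_f)}
#'                      {s_B/d_c + (s_A - s_B)/d_f}.}
#'
#' @param N self gene copy number (>= 1).
#' @param s_A,s_B per-copy synthesis rates with `s_A >= s_B`.
#' @param d_f,d_c free-pool and complex degradation rates (> 0).
#' @return dimensionless fold change of the tagged total.
#' @examples
#' flux_limit_fold(20, 1, 1, 5, 1) # 1/20 + 19/100 = 0.24
#' @export
flux_limit_fold <- function(N, s_A, s_B, d_f, d_c) {
  check_number(N, "N", min = 1)
  check_number(d_f, "d_f", min = 0, strict_min = TRUE)
  check_number(d_c, "d_c", min = 0, strict_min = TRUE)
  if (s_A < s_B || N * s_A < s_B)
    stopf("flux-limit formula requires the partner-limited regime (s_A >= s_B)")
  num <- s_B / (N * d_c) + (N * s_A - s_B) / (N * d_f)
  den <- s_B / d_c + (s_A - s_B) / d_f
  num / den
}

#' Fit model parameter ratios to observed perturbation fold changes
#'
#' Least-squares fit in log-fold space of up to three free parameters --
#' the synthesis ratio `s_A/s_B`, the stability ratio `d_free/d_complex`
#' (applied to both subunits), and `k_on` -- holding all other parameters at
#' the values of `fixed`. Optimization is multi-start Nelder-Mead over a
#' fixed grid of log-space starting points, so the fit is deterministic.
#'
#' @param observations data.frame with columns `kind`, `value`,
#'   `observable`, `fold` (one perturbation experiment per row, e.g. the
#'   multicopy-self / partner-deletion / multicopy-partner triplet).
#' @param fixed a [heterodimer_model()] supplying every non-free parameter
#'   and the baseline copy numbers.
#' @param free character subset of `c("s_ratio", "d_ratio", "k_on")`.
#' @return list with `model` (best-fit model), `par` (named fitted values),
#'   `residuals` (log observed minus log predicted), `rss` and `converged`.
#' @export
fit_parameters <- function(observations, fixed,
                           free = c("d_ratio")) {
  stopifnot(inherits(fixed, "heterodimer_model"))
  allowed <- c("s_ratio", "d_ratio", "k_on")
  if (!length(free) || !all(free %in% allowed))
    stopf("free parameters must be a nonempty subset of: %s",
          paste(allowed, collapse = ", "))
  req <- c("kind", "observable", "fold")
  missing <- setdiff(req, names(observations))
  if (length(missing))
    stopf("observations table is missing column(s): %s",
          paste(missing, collapse = ", "))
  if (nrow(observations) < length(free))
    stopf("under-determined fit: %d observation(s) for free parameter(s) %s",
          nrow(observations), paste(free, collapse = ", "))
  if (any(observations$fold <= 0)) stopf("observed folds must be > 0")

  build <- function(logpar) {
    m <- fixed
    p <- setNames(exp(logpar), free)
    if ("s_ratio" %in% free) m$s_A <- m$s_B * p[["s_ratio"]]
    if ("d_ratio" %in% free) {
      m$d_free_A <- m$d_complex * p[["d_ratio"]]
      m$d_free_B <- m$d_complex * p[["d_ratio"]]
    }
    if ("k_on" %in% free) m$k_on <- p[["k_on"]]
    m
  }
  predict_folds <- function(m) {
    vapply(seq_len(nrow(observations)), function(i) {
      o <- observations[i, ]
      fold_change(m, o$kind,
                  value = if (!is.null(o$value) && !is.na(o$value)) o$value,
                  observable = o$observable)
    }, numeric(1))
  }
  objective <- function(logpar) {
    pred <- tryCatch(predict_folds(build(logpar)), error = function(e) NULL)
    if (is.null(pred) || any(!is.finite(pred)) || any(pred <= 0)) return(1e10)
    sum((log(observations$fold) - log(pred))^2)
  }

  starts <- list(s_ratio = log(c(0.5, 1.5, 5)),
                 d_ratio = log(c(1.5, 5, 20)),
                 k_on = log(c(1, 100, 1e4)))
  grid <- expand.grid(starts[free], KEEP.OUT.ATTRS = FALSE)
  best <- NULL
  for (i in seq_len(nrow(grid))) {
    p0 <- as.numeric(grid[i, ])
    fit <- if (length(free) == 1L)
      stats::optim(p0, objective, method = "Brent",
                   lower = log(1e-4), upper = log(1e8))
    else
      stats::optim(p0, objective, method = "Nelder-Mead",
                   control = list(maxit = 2000, reltol = 1e-12))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (length(free) > 1L) {
    # polish the grid winner: restarted simplex then quasi-Newton
    polish <- stats::optim(best$par, objective, method = "Nelder-Mead",
                           control = list(maxit = 2000, reltol = 1e-14))
    if (polish$value < best$value) best <- polish
    polish <- suppressWarnings(
      stats::optim(best$par, objective, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-14)))
    if (polish$value < best$value) best <- polish
  }
  m_best <- build(best$par)
  pred <- predict_folds(m_best)
  list(model = m_best,
       par = setNames(exp(best$par), free),
       residuals = log(observations$fold) - log(pred),
       rss = best$value,
       converged = best$convergence == 0)
}
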