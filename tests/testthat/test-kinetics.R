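default_like <- function(...) {
  args <- utils::modifyList(
    list(s_A = 1.5, s_B = 1.0, d_free_A = 5, d_free_B = 5,
         d_complex = 1, k_on = 100), list(...))
  do.call(heterodimer_model, args)
}

test_that("steady state matches the closed form and an ODE integration", {
  st <- steady_state(default_like())
  expect_equal(st$A_free, 0.15, tolerance = 1e-9)
  expect_equal(st$B_free, 0.05, tolerance = 1e-9)
  expect_equal(st$C, 0.75, tolerance = 1e-9)
  expect_equal(st$tagged_A_free + st$tagged_C, 0.90, tolerance = 1e-9)

  ode <- oracle_steady_ode(default_like())
  expect_equal(st$A_free, ode$A, tolerance = 1e-6)
  expect_equal(st$B_free, ode$B, tolerance = 1e-6)
  expect_equal(st$C, ode$C, tolerance = 1e-6)
})

test_that("steady state handles degenerate regimes", {
  zero <- steady_state(default_like(s_A = 0, s_B = 0))
  expect_equal(unlist(zero), c(A_free = 0, B_free = 0, C = 0,
                               tagged_A_free = 0, tagged_C = 0))
  nok <- steady_state(default_like(k_on = 0))
  expect_equal(nok$A_free, 1.5 / 5)
  expect_equal(nok$B_free, 1.0 / 5)
  expect_equal(nok$C, 0)
  expect_error(steady_state(default_like(d_complex = 0)), "never degraded")
})

test_that("flux balance holds at steady state, including with dissociation", {
  withr::with_seed(9, {
    for (i in 1:20) {
      m <- default_like(s_A = runif(1, 0.5, 3), s_B = runif(1, 0.5, 3),
                        N_A = sample(1:30, 1), N_B = sample(1:30, 1),
                        d_free_A = runif(1, 1, 10), d_free_B = runif(1, 1, 10),
                        d_complex = runif(1, 0.1, 2),
                        k_on = 10^runif(1, 0, 3), k_off = runif(1, 0, 2),
                        tagged_copies_A = 1)
      st <- steady_state(m)
      # recompute the balance equations here, independent of the solver
      fA <- m$N_A * m$s_A - m$d_free_A * st$A_free -
        m$k_on * st$A_free * st$B_free + m$k_off * st$C
      fB <- m$N_B * m$s_B - m$d_free_B * st$B_free -
        m$k_on * st$A_free * st$B_free + m$k_off * st$C
      fC <- m$k_on * st$A_free * st$B_free - (m$k_off + m$d_complex) * st$C
      scale <- max(m$N_A * m$s_A, m$N_B * m$s_B)
      expect_lt(max(abs(c(fA, fB, fC))) / scale, 1e-9)
    }
  })
})

test_that("perturbations edit the intended fields only", {
  m <- default_like()
  self <- perturb(m, "multicopy_self", 20)
  expect_equal(self$N_A, 20)
  expect_equal(self$tagged_copies_A, 1)
  expect_equal(perturb(m, "multicopy_partner", 20)$N_B, 20)
  expect_equal(perturb(m, "partner_deletion")$N_B, 0)
  pd <- perturb(m, "proteasome_defect", 0)
  expect_equal(pd$d_free_A, m$d_complex)
  expect_equal(pd$d_free_B, m$d_complex)
  half <- perturb(m, "proteasome_defect", 0.5)
  expect_equal(half$d_free_A, 1 + 0.5 * (5 - 1))
  expect_error(perturb(m, "heat_shock"), "unknown perturbation")
  expect_error(perturb(m, "proteasome_defect", 2), "0, 1")
})

test_that("default-calibration fold changes hit the derived values", {
  m <- default_like()
  expect_equal(fold_change(m, "multicopy_self", 20), 0.3774,
               tolerance = 1e-4)
  expect_equal(fold_change(m, "partner_deletion"), 1 / 3, tolerance = 1e-9)
  expect_equal(fold_change(m, "multicopy_partner", 20), 1.6489,
               tolerance = 1e-4)
  # cross-check the multicopy-self state against the ODE oracle
  ode <- oracle_steady_ode(perturb(m, "multicopy_self", 20))
  expect_equal(fold_change(m, "multicopy_self", 20),
               ((ode$A + ode$C) / 20) / 0.90, tolerance = 1e-5)
})

test_that("self-dosage fold is non-increasing and needs the stability gap", {
  m <- default_like()
  folds <- vapply(c(1, 2, 5, 10, 20, 50), function(N)
    fold_change(m, "multicopy_self", N), numeric(1))
  expect_equal(folds[1], 1, tolerance = 1e-9)
  expect_true(all(diff(folds) <= 1e-12))

  # no stability difference, no compensation: exact linear birth-death
  flat <- default_like(d_free_A = 1, d_free_B = 1, d_complex = 1)
  for (N in c(2, 5, 20, 50))
    expect_equal(fold_change(flat, "multicopy_self", N), 1, tolerance = 1e-9)
})

test_that("responses to partner dosage are bidirectional at both levels", {
  m <- default_like()  # s_A > s_B
  expect_gt(fold_change(m, "multicopy_partner", 20), 1)
  expect_lt(fold_change(m, "multicopy_self", 20), 1)
  expect_lt(fold_change(m, "multicopy_self", 20, observable = "tagged_complex"), 1)
  expect_gt(fold_change(m, "multicopy_partner", 20, observable = "tagged_complex"), 1)
})

test_that("CHX chase decays as the two-pool model predicts", {
  times <- c(0, 1, 2, 4, 6)
  # decoupled single pool: exact exponential at the free rate
  solo <- simulate_chx(default_like(k_on = 0, s_B = 0, d_free_A = 2),
                       times)
  expect_equal(solo$relative_levels, exp(-2 * times), tolerance = 1e-7)

  single <- simulate_chx(default_like(), times)
  multi <- simulate_chx(perturb(default_like(), "multicopy_self", 20), times)
  expect_equal(single$relative_levels[1], 1)
  expect_true(all(multi$relative_levels[-1] < single$relative_levels[-1]))

  flat <- default_like(d_free_A = 1, d_free_B = 1, d_complex = 1)
  s1 <- simulate_chx(flat, times)
  s2 <- simulate_chx(perturb(flat, "multicopy_self", 20), times)
  expect_equal(s1$relative_levels, s2$relative_levels, tolerance = 1e-8)
})

test_that("flux-limit closed form and fast-association steady state agree", {
  expect_equal(flux_limit_fold(1, 1.5, 1, 5, 1), 1.0)
  expect_equal(flux_limit_fold(20, 1, 1, 1, 1), 1.0)
  expect_equal(flux_limit_fold(20, 1, 1, 5, 1), 0.24, tolerance = 1e-12)
  expect_error(flux_limit_fold(2, 0.5, 1, 5, 1), "regime")

  for (sA in c(1, 1.5, 3))
    for (df in c(2, 5, 10))
      for (N in c(2, 10, 50)) {
        m <- default_like(s_A = sA, s_B = 1, d_free_A = df, d_free_B = df,
                          d_complex = 1, k_on = 1e6)
        fc <- fold_change(m, "multicopy_self", N)
        fl <- flux_limit_fold(N, sA, 1, df, 1)
        expect_lt(abs(fc / fl - 1), 0.02)
      }
})

test_that("parameter fitting recovers the stability ratio", {
  m <- default_like()
  obs <- data.frame(
    kind = c("multicopy_self", "partner_deletion", "multicopy_partner"),
    value = c(20, NA, 20), observable = "tagged_total_A",
    fold = c(fold_change(m, "multicopy_self", 20),
             fold_change(m, "partner_deletion"),
             fold_change(m, "multicopy_partner", 20)))
  start <- default_like(s_A = 1, d_free_A = 2, d_free_B = 2)
  fit <- fit_parameters(obs, fixed = start, free = c("s_ratio", "d_ratio"))
  expect_true(fit$converged)
  expect_equal(unname(fit$par["d_ratio"]), 5, tolerance = 0.05)
  expect_equal(unname(fit$par["s_ratio"]), 1.5, tolerance = 0.05)

  expect_error(fit_parameters(obs[1, ], fixed = start,
                              free = c("s_ratio", "d_ratio")),
               "under-determined")
})

test_that("model configuration round-trips through YAML", {
  m <- default_model()
  expect_s3_class(m, "heterodimer_model")
  expect_equal(m$s_A, 1.5)
  expect_equal(m$k_on, 100)
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("s_A: 1", "s_B: 1", "d_free_A: 5", "d_free_B: 5",
               "d_complex: 1", "k_on: 10", "bogus_key: 3"), path)
  expect_error(read_model(path), "unknown model key")
})
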