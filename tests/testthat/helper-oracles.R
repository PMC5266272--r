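# Independent oracles used across test files.

# Brute-force one-tailed Mann-Whitney p-value (y greater) by complete
# enumeration, scoring each assignment with the pair-counting U statistic
# (ties count 1/2) rather than rank sums.
oracle_mw_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled)
  ny <- length(y)
  ustat <- function(xs, ys)
    sum(outer(ys, xs, ">")) + 0.5 * sum(outer(ys, xs, "=="))
  u_obs <- ustat(x, y)
  idx <- utils::combn(n, ny)
  u_all <- apply(idx, 2, function(k) ustat(pooled[-k], pooled[k]))
  mean(u_all >= u_obs - 1e-9)
}

# Long ODE integration of the heterodimer model, an independent route to
# the steady state (the closed-form solver never integrates).
oracle_steady_ode <- function(model, t_end = 2000) {
  deriv <- function(t, y, p) {
    A <- y[1]; B <- y[2]; C <- y[3]
    list(c(
      model$N_A * model$s_A - model$d_free_A * A -
        model$k_on * A * B + model$k_off * C,
      model$N_B * model$s_B - model$d_free_B * B -
        model$k_on * A * B + model$k_off * C,
      model$k_on * A * B - (model$k_off + model$d_complex) * C))
  }
  sol <- deSolve::ode(y = c(A = 0, B = 0, C = 0), times = c(0, t_end),
                      func = deriv, parms = NULL, rtol = 1e-12, atol = 1e-14)
  as.list(sol[nrow(sol), c("A", "B", "C")])
}
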