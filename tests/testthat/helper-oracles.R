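# Independent oracles used to validate the implementation. These must stay
# independent of the code paths they check: plain quadrature, explicit Euler
# integration of the two-state master equation, and a tau-grid exponential
# search with exact linear least squares for the amplitude and baseline.

trapezoid <- function(t, y) {
  n <- length(t)
  sum(diff(t) * (y[-1] + y[-n]) / 2)
}

# Explicit Euler integration of dp/dt = beta(V) (1 - p) - alpha(V) p for the
# occupancy p of the inner position, starting from the steady state at the
# holding potential. Returns the occupancy trajectory end point and the
# charge moved, Qmax * (p_end - p0).
euler_two_state <- function(cm, V, holding_mV, t_end = 0.3, dt = 1e-6) {
  sigma <- cm$sigma_mV
  u <- function(v) (v - cm$V_half_mV) / sigma
  a <- cm$k0_per_s * exp(u(V) / 2)
  b <- cm$k0_per_s * exp(-u(V) / 2)
  p0 <- 1 / (1 + exp(u(holding_mV)))
  p <- p0
  n <- round(t_end / dt)
  for (i in seq_len(n)) {
    p <- p + dt * (b * (1 - p) - a * p)
  }
  list(p_end = p, p0 = p0, delta_Q = cm$Qmax_nC * (p - p0))
}

# Brute-force SSE search for I(t) = A exp(-t/tau) + b: scan tau on a log grid
# and solve (A, b) exactly by linear least squares at each tau.
grid_fit_exponential <- function(tt, y, tau_lo, tau_hi, n_tau = 600) {
  taus <- exp(seq(log(tau_lo), log(tau_hi), length.out = n_tau))
  best <- list(sse = Inf)
  for (tau in taus) {
    x <- exp(-tt / tau)
    X <- cbind(x, 1)
    cf <- tryCatch(solve(crossprod(X), crossprod(X, y)),
                   error = function(e) NULL)
    if (is.null(cf)) next
    r <- y - X %*% cf
    sse <- sum(r * r)
    if (sse < best$sse) {
      best <- list(A = cf[1], tau = tau, b = cf[2], sse = sse)
    }
  }
  best
}

hill_current <- function(S, Imax, K, p = 1) Imax * S^p / (S^p + K^p)

# Two-substrate steady-state model recomputed directly (mirror of the
# documented generative formula, kept separate from the package's code).
model_two_substrate <- function(G_uM, B_mM, prm, factor = 1) {
  g <- G_uM / prm$K_G_uM
  b <- B_mM / prm$K_B_mM
  supp <- if (is.infinite(prm$K_inh_mM)) 1 else {
    (1 + g) / (1 + g + B_mM / prm$K_inh_mM)
  }
  factor * (prm$I_G_nA * g * supp + prm$I_B_nA * b) / (1 + g + b)
}
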