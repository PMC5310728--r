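# Independent oracles used across the suite.

# Free integrase by scalar root-finding on the conservation equation
# f(I) = I + I * R(I) / K_ir - I_tot with R(I) = R_tot - I_tot + I,
# independent of the closed-form quadratic root in the package.
oracle_free_I <- function(I_tot, R_tot, K_ir) {
  if (I_tot == 0 || R_tot == 0) return(I_tot)
  f <- function(I) I + I * (R_tot - I_tot + I) / K_ir - I_tot
  stats::uniroot(f, c(0, I_tot), tol = 1e-15 * max(I_tot, 1))$root
}

# Detailed-balance fixed point constructed from equilibrium relations alone
# (free PB = free LR = z because substrate and product are isoenergetic and
# every cycle product is 1), not from time integration.
oracle_fixed_point <- function(tot, p) {
  fp <- free_proteins(tot, p)
  phi4 <- (fp$I / p$K_bI)^4
  psi4 <- (fp$IR / p$K_bI)^4
  den_PB <- 1 + phi4 + psi4 + (fp$I * fp$IR)^2 / p$K_bI^4
  den_LR <- 1 + phi4 + psi4 + (fp$I * fp$IR)^2 / p$K_bI_i^4
  z <- tot$D_tot / (den_PB + p$K_r2 * psi4 + den_LR + p$K_r1 * phi4)
  LRI1 <- p$K_r1 * z * phi4
  PBIR1 <- p$K_r2 * z * psi4
  c(LRI1 = LRI1, PBIR1 = PBIR1, PB_tot = z * den_PB + PBIR1)
}

# Fixed-step classical Runge-Kutta integration of the slow system; an
# integrator entirely independent of deSolve and of the matrix-exponential
# endpoint path.
oracle_rk4 <- function(spec, params, t_end, dt) {
  free <- free_proteins(spec$totals, params)
  s <- if (spec$substrate == "PB") c(0, 0, spec$totals$D_tot) else c(0, 0, 0)
  n <- ceiling(t_end / dt)
  dt <- t_end / n
  f <- function(y) slow_derivatives(0, y, spec$totals, params, free = free)
  for (i in seq_len(n)) {
    k1 <- f(s); k2 <- f(s + dt / 2 * k1); k3 <- f(s + dt / 2 * k2)
    k4 <- f(s + dt * k3)
    s <- s + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  s
}

# Endpoint predictions via the stiff ODE solver, independent of the
# matrix-exponential path used inside the fitting layer.
predict_endpoints_oracle <- function(params, design) {
  vapply(seq_len(nrow(design)), function(i) {
    spec <- experiment_spec(design$substrate[i],
                            D_tot = design$D_tot_nM[i] / 1e3,
                            I_tot = design$I_tot_nM[i] / 1e3,
                            R_tot = design$R_tot_nM[i] / 1e3,
                            t_end = design$t_h[i],
                            output_grid = c(0, design$t_h[i]))
    tr <- simulate_time_course(spec, params)
    tr$product_fraction[nrow(tr)]
  }, numeric(1))
}

ref_spec <- function(substrate = "PB", I_tot = 0.4, R_tot = 0, t_end = 3,
                     D_tot = 0.01, ...) {
  experiment_spec(substrate, D_tot = D_tot, I_tot = I_tot, R_tot = R_tot,
                  t_end = t_end, ...)
}

species_names <- c("I", "R", "IR", "PB", "LR", "PBI", "PBIR1", "PBIR2",
                   "PBIRi", "LRI1", "LRI2", "LRIR", "LRIRi")
pb_names <- c("PB", "PBI", "PBIR1", "PBIR2", "PBIRi")
lr_names <- c("LR", "LRI1", "LRI2", "LRIR", "LRIRi")
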