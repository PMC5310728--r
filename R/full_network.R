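#' Unreduced mass-action realization of the reaction scheme
#'
#' Builds the full 13-species elementary reaction network in which the
#' binding steps are explicit reversible reactions rather than
#' pre-equilibrated isotherms, and free integrase, RDF and IR are dynamic.
#' This network is the validation oracle for the rapid-equilibrium
#' reduction: in the limit of fast binding its trajectories converge to
#' those of the reduced model, and unlike the reduced model it conserves
#' protein exactly (no neglect of DNA-bound integrase/RDF).
#'
#' The four-protomer binding steps are realized as single elementary
#' reactions with fourth-order protein kinetics (e.g. `PB + 4I <-> PBI`),
#' matching the reduced model's single-step isotherms so that the two
#' models share identical equilibria by construction. Every fast step is
#' given dissociation rate `k_fast` (per hour) and the association rate that
#' reproduces its dissociation constant, so equilibria are independent of
#' `k_fast` while the binding relaxation time scales as `1/k_fast`.
#'
#' @param params An [integrase_params()] object.
#' @param k_fast Magnitude of the fast-step dissociation rates, per hour
#'   (default `1e4`, i.e. binding equilibrates on a timescale of fractions
#'   of a second, far below the strand-exchange timescale `1/k_plus_r`).
#' @return An object of class `full_network`: species names, stoichiometry
#'   matrix, reactant/product order matrices and rate constants.
#' @export
full_network <- function(params, k_fast = 1e4) {
  species <- c("I", "R", "IR", "PB", "LR", "PBI", "PBIR1", "PBIR2", "PBIRi",
               "LRI1", "LRI2", "LRIR", "LRIRi")
  rx <- list(
    # name, reactants (named stoich), products, kf, kb
    list("ir",   c(I = 1, R = 1),          c(IR = 1),
         k_fast / params$K_ir, k_fast),
    list("b1",   c(PB = 1, I = 4),         c(PBI = 1),
         k_fast / params$K_bI^4, k_fast),
    list("b2",   c(LR = 1, I = 4),         c(LRI2 = 1),
         k_fast / params$K_bI^4, k_fast),
    list("b3",   c(LR = 1, IR = 4),        c(LRIR = 1),
         k_fast / params$K_bI^4, k_fast),
    list("b4",   c(PB = 1, IR = 4),        c(PBIR2 = 1),
         k_fast / params$K_bI^4, k_fast),
    list("bi_PB", c(PB = 1, I = 2, IR = 2), c(PBIRi = 1),
         k_fast / params$K_bI^4, k_fast),
    list("bi_LR", c(LR = 1, I = 2, IR = 2), c(LRIRi = 1),
         k_fast / params$K_bI_i^4, k_fast),
    list("r1",   c(PBI = 1),               c(LRI1 = 1),
         params$k_plus_r, params$k_minus_r1),
    list("r2",   c(LRIR = 1),              c(PBIR1 = 1),
         params$k_plus_r, params$k_minus_r2),
    list("syn",  c(LRI1 = 1),              c(LRI2 = 1),
         params$k_plus_syn, params$k_minus_syn),
    list("synr", c(PBIR1 = 1),             c(PBIR2 = 1),
         params$k_plus_synr, params$k_minus_synr))
  n <- length(species)
  m <- length(rx)
  Vr <- Vp <- matrix(0, n, m, dimnames = list(species, NULL))
  kf <- kb <- numeric(m)
  names_rx <- character(m)
  for (j in seq_len(m)) {
    names_rx[j] <- rx[[j]][[1]]
    Vr[names(rx[[j]][[2]]), j] <- rx[[j]][[2]]
    Vp[names(rx[[j]][[3]]), j] <- rx[[j]][[3]]
    kf[j] <- rx[[j]][[4]]
    kb[j] <- rx[[j]][[5]]
  }
  structure(list(species = species, reactions = names_rx,
                 Vr = Vr, Vp = Vp, S = Vp - Vr, kf = kf, kb = kb,
                 k_fast = k_fast, params = params),
            class = "full_network")
}

# mass-action net rates for all reactions at state y (clamped at 0)
network_rates <- function(net, y) {
  y <- pmax(y, 0)
  fwd <- net$kf * apply(y ^ net$Vr, 2, prod)
  rev <- net$kb * apply(y ^ net$Vp, 2, prod)
  fwd - rev
}

#' Integrate the full network
#'
#' Stiff integration of all 13 species. Initial state: naked substrate DNA
#' plus free proteins (`I = I_tot`, `R = R_tot`, `IR = 0`); the fast steps
#' equilibrate within the first moments of the run. Events add or remove
#' the difference between the new and current total to the free protein
#' pool.
#'
#' @param net A [full_network()].
#' @param spec An [experiment_spec()].
#' @param rtol,atol Solver tolerances (defaults `1e-8`, `1e-12`).
#' @return A data frame with `t_h`, the 13 species (uM) and
#'   `product_fraction` defined as for [simulate_time_course()].
#' @export
simulate_full_network <- function(net, spec, rtol = 1e-8, atol = 1e-12) {
  y0 <- stats::setNames(numeric(13), net$species)
  y0["I"] <- spec$totals$I_tot
  y0["R"] <- spec$totals$R_tot
  y0[if (spec$substrate == "PB") "PB" else "LR"] <- spec$totals$D_tot
  rhs <- function(t, y, parms) list(as.numeric(net$S %*% network_rates(net, y)))
  segs <- segment_table(spec)
  grid <- spec$output_grid
  out_all <- matrix(NA_real_, length(grid), 13,
                    dimnames = list(NULL, net$species))
  y <- y0
  prev_tot <- spec$totals
  for (i in seq_along(segs)) {
    seg <- segs[[i]]
    if (i > 1) {
      for (f in c("I_tot", "R_tot")) {
        d <- seg$totals[[f]] - prev_tot[[f]]
        if (d != 0) {
          sp <- if (f == "I_tot") "I" else "R"
          y[sp] <- y[sp] + d
          if (y[sp] < 0)
            stop("event would remove more free ", sp, " than available")
        }
      }
    }
    prev_tot <- seg$totals
    idx <- which(grid >= seg$from & (grid < seg$to | i == length(segs)))
    tms <- sort(unique(c(seg$from, grid[idx], seg$to)))
    if (length(tms) > 1) {
      out <- deSolve::ode(y, tms, rhs, NULL, rtol = rtol, atol = atol,
                          method = "lsoda", maxsteps = 50000)
      if (attr(out, "istate")[1] < 0)
        stop("full-network integrator failed near t = ",
             signif(out[nrow(out), 1], 4), " h")
      if (length(idx))
        out_all[idx, ] <- out[match(grid[idx], out[, 1]), -1, drop = FALSE]
      y <- out[nrow(out), -1]
    } else if (length(idx)) {
      out_all[idx, ] <- rep(y, each = length(idx))
    }
  }
  D <- spec$totals$D_tot
  pb_frac <- rowSums(out_all[, .pb_species, drop = FALSE]) / D
  prod_frac <- if (spec$substrate == "PB") 1 - pb_frac else pb_frac
  data.frame(t_h = grid, out_all,
             product_fraction = pmin(pmax(prod_frac, 0), 1),
             check.names = FALSE)
}

#' Wegscheider cycle products of the elementary network
#'
#' Evaluates the product of forward/backward rate-constant ratios around
#' the two closed cycles of the network (binding, strand exchange,
#' conformational change, unbinding). Both products are 1 for a network
#' built from a thermodynamically closed parameter set.
#'
#' @param net A [full_network()].
#' @return Named numeric vector with the two cycle products.
#' @export
network_cycle_products <- function(net) {
  K <- stats::setNames(net$kf / net$kb, net$reactions)
  c(cycle_PB_LR = K[["b1"]] * K[["r1"]] * K[["syn"]] / K[["b2"]],
    cycle_LR_PB = K[["b3"]] * K[["r2"]] * K[["synr"]] / K[["b4"]])
}

#' Deviation of the reduced model from the full network
#'
#' For each fast-step rate magnitude, integrates the full network and the
#' reduced model on a common time grid and reports the sup-norm over time
#' of the absolute difference in product fraction. The deviation must
#' shrink as binding becomes fast relative to strand exchange; its floor is
#' set by the reduced model's neglect of DNA-bound protein in the free
#' integrase/RDF balance.
#'
#' @param spec An [experiment_spec()].
#' @param params An [integrase_params()] object.
#' @param k_fast_values Fast-step rate magnitudes to test, per hour.
#' @return Data frame with columns `k_fast` and `max_abs_deviation`.
#' @export
compare_reduced_full <- function(spec, params,
                                 k_fast_values = c(1e2, 1e3, 1e4)) {
  red <- simulate_time_course(spec, params)
  dev <- vapply(k_fast_values, function(kf) {
    full <- simulate_full_network(full_network(params, k_fast = kf), spec)
    max(abs(full$product_fraction - red$product_fraction))
  }, numeric(1))
  data.frame(k_fast = k_fast_values, max_abs_deviation = dev)
}
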