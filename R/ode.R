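#' Specify a recombination experiment
#'
#' @param substrate `"PB"` (attP+attB plasmid) or `"LR"` (attL+attR plasmid).
#' @param D_tot Total plasmid DNA, uM.
#' @param I_tot Total integrase monomer, uM.
#' @param R_tot Total RDF monomer, uM.
#' @param t_end End of the simulated time window, hours.
#' @param events Optional list of events, each a list
#'   `list(time = <hours>, field = "I_tot"|"R_tot", value = <uM>)`, applied
#'   in order; times must be strictly increasing and inside `(0, t_end)`.
#'   At an event the named total is replaced, the slow variables are carried
#'   across unchanged and the free proteins are re-resolved.
#' @param output_grid Optional numeric vector of output times (hours) in
#'   `[0, t_end]`; defaults to 200 log-spaced points (experiments spanning
#'   fast initial kinetics and very slow relaxations are best viewed on a
#'   logarithmic time axis).
#' @return An object of class `experiment_spec`.
#' @export
experiment_spec <- function(substrate = c("PB", "LR"), D_tot, I_tot,
                            R_tot = 0, t_end, events = NULL,
                            output_grid = NULL) {
  substrate <- match.arg(substrate)
  tot <- totals(I_tot, R_tot, D_tot)
  if (!is.finite(t_end) || t_end <= 0) stop("t_end must be positive")
  if (!is.null(events)) {
    tev <- vapply(events, function(e) as.numeric(e$time), numeric(1))
    if (any(diff(tev) <= 0) || any(tev <= 0) || any(tev >= t_end))
      stop("event times must be strictly increasing and within (0, t_end)")
    for (e in events) {
      if (!e$field %in% c("I_tot", "R_tot"))
        stop("event field must be 'I_tot' or 'R_tot'")
      if (!is.finite(e$value) || e$value < 0)
        stop("event value must be non-negative")
    }
  }
  if (is.null(output_grid)) {
    output_grid <- c(0, 10^seq(log10(t_end) - 5, log10(t_end),
                               length.out = 200))
  } else {
    output_grid <- sort(unique(as.numeric(output_grid)))
    if (min(output_grid) < 0 || max(output_grid) > t_end)
      stop("output_grid must lie within [0, t_end]")
  }
  structure(list(substrate = substrate, totals = tot, t_end = t_end,
                 events = events, output_grid = output_grid),
            class = "experiment_spec")
}

# initial slow state: at t = 0 all DNA is naked substrate
initial_slow <- function(spec) {
  if (spec$substrate == "PB")
    c(LRI1 = 0, PBIR1 = 0, PB_tot = spec$totals$D_tot)
  else
    c(LRI1 = 0, PBIR1 = 0, PB_tot = 0)
}

#' Time derivatives of the slow variables
#'
#' The right-hand side of the three slow ODEs. Only the slow steps
#' contribute: r1 (PBI <-> LRI1), r2 (LRIR <-> PBIR1), syn (LRI1 <-> LRI2)
#' and synr (PBIR1 <-> PBIR2); the fast complexes entering these fluxes are
#' resolved through [fast_species()]. Net r1 flux consumes the PB pool and
#' net r2 flux produces it:
#' `d(PB_tot)/dt = -(net r1) + (net r2)`.
#'
#' @param t Time, hours (unused: the system is autonomous; kept for solver
#'   compatibility).
#' @param slow Numeric vector `c(LRI1, PBIR1, PB_tot)`, uM.
#' @param totals A [totals()] object.
#' @param params An [integrase_params()] object.
#' @param free Optional precomputed [free_proteins()] result.
#' @return Numeric vector of derivatives `c(dLRI1, dPBIR1, dPB_tot)`,
#'   uM per hour.
#' @export
slow_derivatives <- function(t, slow, totals, params, free = NULL) {
  s <- fast_species(slow, totals, params, free = free)
  r1 <- params$k_plus_r * s[["PBI"]] - params$k_minus_r1 * s[["LRI1"]]
  r2 <- params$k_plus_r * s[["LRIR"]] - params$k_minus_r2 * s[["PBIR1"]]
  syn <- params$k_plus_syn * s[["LRI1"]] - params$k_minus_syn * s[["LRI2"]]
  synr <- params$k_plus_synr * s[["PBIR1"]] -
    params$k_minus_synr * s[["PBIR2"]]
  c(LRI1 = r1 - syn, PBIR1 = r2 - synr, PB_tot = -r1 + r2)
}

# Per-segment constant-coefficient form. Because the free proteins (hence
# the binding weights) depend only on the totals, the slow system within one
# segment is exactly linear: d(slow)/dt = A slow + b. Returns A (3x3) and b.
linear_system <- function(totals, params, free = NULL) {
  if (is.null(free)) free <- free_proteins(totals, params)
  w <- binding_weights(free, params)
  D <- totals$D_tot
  a1 <- params$k_plus_r * w$phi4 / w$den_PB    # PBI flux per unit fast PB pool
  a2 <- params$k_plus_r * w$psi4 / w$den_LR    # LRIR flux per unit fast LR pool
  cs <- params$k_minus_syn * w$phi4 / w$den_LR # LRI2 flux per unit fast LR pool
  cr <- params$k_minus_synr * w$psi4 / w$den_PB
  A <- matrix(c(
    -params$k_minus_r1 - params$k_plus_syn - cs, -a1,                  a1 - cs,
    -a2, -params$k_minus_r2 - params$k_plus_synr - cr,                -a2 + cr,
    params$k_minus_r1 - a2,                       a1 - params$k_minus_r2,
    -a1 - a2),
    nrow = 3, byrow = TRUE)
  b <- c(cs * D, a2 * D, a2 * D)
  list(A = A, b = b)
}

# Exact propagation of the slow state over a time step via the augmented
# matrix exponential exp([[A, b], [0, 0]] t) acting on (slow, 1).
propagate_linear <- function(slow, dt, sys) {
  if (dt == 0) return(slow)
  M <- rbind(cbind(sys$A, sys$b), 0)
  E <- as.matrix(Matrix::expm(M * dt))
  out <- E %*% c(slow, 1)
  stats::setNames(out[1:3], c("LRI1", "PBIR1", "PB_tot"))
}

# segment boundaries implied by the event list
segment_table <- function(spec) {
  ev_t <- if (is.null(spec$events)) numeric(0) else
    vapply(spec$events, function(e) e$time, numeric(1))
  starts <- c(0, ev_t)
  ends <- c(ev_t, spec$t_end)
  tot <- spec$totals
  segs <- vector("list", length(starts))
  for (i in seq_along(starts)) {
    if (i > 1) {
      e <- spec$events[[i - 1]]
      tot[[e$field]] <- e$value
    }
    segs[[i]] <- list(from = starts[i], to = ends[i],
                      totals = totals(tot$I_tot, tot$R_tot, tot$D_tot))
  }
  segs
}

#' Integrate the slow system over an experiment
#'
#' Integrates the three slow ODEs over `[0, t_end]` with a stiff-capable
#' solver, restarting at each event with the updated totals (the slow state
#' is carried across the event; free proteins are re-resolved). The full
#' species state is reconstructed on the output grid through
#' [fast_species()].
#'
#' @param spec An [experiment_spec()].
#' @param params An [integrase_params()] object.
#' @param rtol,atol Relative and absolute solver tolerances (defaults
#'   `1e-8` and `1e-12` uM; the slow steps span hours to days, so an
#'   implicit/stiff method is used).
#' @param method Solver method passed to [deSolve::ode()] (default
#'   `"lsoda"`, which switches to a BDF scheme on stiffness).
#' @return An object of class `recomb_trajectory`: a data frame with column
#'   `t_h`, one column per species (uM) and `product_fraction`
#'   (`LR_tot/D_tot` for PB-substrate experiments, `PB_tot/D_tot` for
#'   LR-substrate ones; [rdf_switch()] reports the PB fraction), with the
#'   spec and params attached as attributes.
#' @export
simulate_time_course <- function(spec, params, rtol = 1e-8, atol = 1e-12,
                                 method = "lsoda") {
  stopifnot(inherits(spec, "experiment_spec"))
  segs <- segment_table(spec)
  grid <- spec$output_grid
  slow <- initial_slow(spec)
  rows <- matrix(NA_real_, nrow = length(grid), ncol = 3,
                 dimnames = list(NULL, c("LRI1", "PBIR1", "PB_tot")))
  seg_of <- integer(length(grid))
  for (i in seq_along(segs)) {
    seg <- segs[[i]]
    free <- free_proteins(seg$totals, params)
    idx <- which(grid >= seg$from & (grid < seg$to | i == length(segs)))
    tms <- sort(unique(c(seg$from, grid[idx], seg$to)))
    if (length(tms) > 1) {
      out <- deSolve::ode(
        y = slow, times = tms,
        func = function(t, y, parms) {
          list(slow_derivatives(t, y, seg$totals, params, free = free))
        },
        parms = NULL, rtol = rtol, atol = atol, method = method)
      if (attr(out, "istate")[1] < 0)
        stop(sprintf(paste0("integrator failed in segment %d near t = %.4g h",
                            " (last state: LRI1=%.4g, PBIR1=%.4g,",
                            " PB_tot=%.4g)"),
                     i, out[nrow(out), 1], out[nrow(out), 2],
                     out[nrow(out), 3], out[nrow(out), 4]))
      if (length(idx))
        rows[idx, ] <- out[match(grid[idx], out[, 1]), -1, drop = FALSE]
      seg_of[idx] <- i
      slow <- out[nrow(out), -1]
    } else {
      if (length(idx)) { rows[idx, ] <- rep(slow, each = length(idx)) }
      seg_of[idx] <- i
    }
  }
  sp <- t(vapply(seq_along(grid), function(j) {
    fast_species(rows[j, ], segs[[seg_of[j]]]$totals, params)
  }, numeric(13)))
  D <- spec$totals$D_tot
  pb_frac <- rowSums(sp[, .pb_species, drop = FALSE]) / D
  prod_frac <- if (spec$substrate == "PB") 1 - pb_frac else pb_frac
  traj <- data.frame(t_h = grid, sp, product_fraction = pmin(pmax(
    prod_frac, 0), 1), check.names = FALSE)
  structure(traj, class = c("recomb_trajectory", "data.frame"),
            spec = spec, params = params)
}

#' Product fraction at a fixed read time
#'
#' Evaluates the recombination extent (product fraction) at `t_read` hours.
#' Within each event segment the slow system has constant coefficients, so
#' the state is propagated exactly with a matrix exponential; the result
#' matches [simulate_time_course()] to within solver tolerance and is used
#' heavily by the fitting layer.
#'
#' @param spec An [experiment_spec()] with `t_end >= t_read`.
#' @param params An [integrase_params()] object.
#' @param t_read Read time in hours (default 3, the standard endpoint assay).
#' @return Product fraction in `[0, 1]`.
#' @export
endpoint_extent <- function(spec, params, t_read = 3) {
  stopifnot(inherits(spec, "experiment_spec"))
  if (t_read > spec$t_end) stop("t_read exceeds t_end of the experiment")
  segs <- segment_table(spec)
  slow <- initial_slow(spec)
  tot <- spec$totals
  for (seg in segs) {
    if (seg$from >= t_read) break
    sys <- linear_system(seg$totals, params)
    slow <- propagate_linear(slow, min(seg$to, t_read) - seg$from, sys)
    tot <- seg$totals
  }
  pb_frac <- slow[["PB_tot"]] / spec$totals$D_tot
  f <- if (spec$substrate == "PB") 1 - pb_frac else pb_frac
  min(max(f, 0), 1)
}

#' @export
print.recomb_trajectory <- function(x, ...) {
  spec <- attr(x, "spec")
  cat(sprintf(
    "Recombination time course: %s substrate, D=%.4g uM, I=%.4g uM, R=%.4g uM\n",
    spec$substrate, spec$totals$D_tot, spec$totals$I_tot, spec$totals$R_tot))
  if (!is.null(spec$events))
    cat(sprintf("  %d event(s); ", length(spec$events)))
  cat(sprintf("%d time points over [0, %.4g] h; final product fraction %.4f\n",
              nrow(x), spec$t_end, x$product_fraction[nrow(x)]))
  invisible(x)
}

#' Plot a simulated time course
#'
#' Shows the total PB and LR pools and the most abundant protein-DNA
#' complexes relative to total DNA, on a logarithmic time axis by default.
#'
#' @param x A `recomb_trajectory`.
#' @param log Axis specification passed to [graphics::matplot()]
#'   (default `"x"`).
#' @param ... Further arguments passed to [graphics::matplot()].
#' @export
plot.recomb_trajectory <- function(x, log = "x", ...) {
  spec <- attr(x, "spec")
  D <- spec$totals$D_tot
  pb <- rowSums(as.matrix(x[, .pb_species])) / D
  lr <- rowSums(as.matrix(x[, .lr_species])) / D
  cols <- c("PBI", "PBIR1", "PBIR2", "LRI1", "LRI2", "LRIR")
  keep <- cols[apply(as.matrix(x[, cols]), 2, max) / D > 0.02]
  y <- cbind(PB_tot = pb, LR_tot = lr, as.matrix(x[, keep, drop = FALSE]) / D)
  t <- x$t_h
  if (grepl("x", log)) t[t == 0] <- NA
  graphics::matplot(t, y, type = "l", lty = c(1, 1, rep(2, length(keep))),
                    col = c("blue", "red", seq_along(keep) + 2), log = log,
                    xlab = "time [h]", ylab = "fraction of total DNA", ...)
  graphics::legend("topleft", legend = colnames(y), bty = "n",
                   lty = c(1, 1, rep(2, length(keep))),
                   col = c("blue", "red", seq_along(keep) + 2), cex = 0.8)
  invisible(x)
}
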