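#' Endpoint titration grid
#'
#' Computes the 3-hour (by default) recombination extent over a grid of
#' integrase and RDF concentrations on one substrate, mirroring the standard
#' endpoint titration assay at 10 nM plasmid.
#'
#' @param substrate `"PB"` or `"LR"`.
#' @param D_tot Total plasmid DNA, uM.
#' @param I_values Integrase totals to scan, uM.
#' @param R_values RDF totals to scan, uM.
#' @param params An [integrase_params()] object.
#' @param t_read Read time, hours (default 3).
#' @return A tidy data frame with columns `substrate`, `I_tot_nM`,
#'   `R_tot_nM`, `t_h`, `product_fraction`, one row per (I, R) pair.
#' @export
titration_grid <- function(substrate, D_tot, I_values, R_values, params,
                           t_read = 3) {
  grid <- expand.grid(I_tot = I_values, R_tot = R_values)
  frac <- mapply(function(I, R) {
    spec <- experiment_spec(substrate, D_tot = D_tot, I_tot = I, R_tot = R,
                            t_end = t_read)
    endpoint_extent(spec, params, t_read = t_read)
  }, grid$I_tot, grid$R_tot)
  data.frame(substrate = substrate,
             I_tot_nM = grid$I_tot * 1e3,
             R_tot_nM = grid$R_tot * 1e3,
             t_h = t_read,
             product_fraction = as.numeric(frac))
}

#' Delayed-RDF switch protocol
#'
#' Runs the PxB reaction without RDF, adds RDF at `t_switch`, and follows
#' the return of the DNA to the PB state. After roughly an hour of the
#' RDF-free reaction most of the DNA sits in the LRI1 product synapse;
#' adding RDF collapses the free integrase pool (sequestration as IR),
#' reverses the strand-exchange step and drains the DNA into the
#' RDF-favoured PB-side complexes, transiently approaching 100% PB -- above
#' the ceiling of the LxR(+RDF) reaction run with RDF present from the
#' start.
#'
#' @param D_tot Total plasmid DNA, uM.
#' @param I_tot Total integrase, uM.
#' @param R_after RDF total set at the switch, uM.
#' @param t_switch Switch time, hours (default 1).
#' @param t_end End of the run, hours (default 10).
#' @param params An [integrase_params()] object.
#' @param ... Passed to [simulate_time_course()].
#' @return List with elements `trajectory` (a `recomb_trajectory` whose
#'   `product_fraction` is the PB fraction) and `max_PB_fraction`, the
#'   maximum of `PB_tot/D_tot` over `t > t_switch`.
#' @export
rdf_switch <- function(D_tot, I_tot, R_after, t_switch = 1, t_end = 10,
                       params, ...) {
  if (t_switch >= t_end) stop("t_switch must be smaller than t_end")
  events <- list(list(time = t_switch, field = "R_tot", value = R_after))
  grid <- sort(unique(c(0, 10^seq(-4, log10(t_end), length.out = 300),
                        t_switch)))
  spec <- experiment_spec("PB", D_tot = D_tot, I_tot = I_tot, R_tot = 0,
                          t_end = t_end, events = events, output_grid = grid)
  traj <- simulate_time_course(spec, params, ...)
  pb_frac <- rowSums(as.matrix(traj[, .pb_species])) / D_tot
  # for the switch protocol the quantity of interest is the return to PB
  traj$product_fraction <- pmin(pmax(pb_frac, 0), 1)
  list(trajectory = traj,
       max_PB_fraction = max(pb_frac[traj$t_h > t_switch]))
}

#' Time to half of the attainable product level
#'
#' The half-time T0.5 of a reaction: the first time the product fraction
#' reaches 50% of its maximum attainable level. The attainable level is the
#' plateau of the time course, detected when the relative change of the
#' product fraction over the last decade of time drops below 0.5%; the
#' crossing is located by interpolation on a log-spaced grid.
#'
#' @param spec An [experiment_spec()]; its `t_end` should comfortably cover
#'   the plateau (allowed reactions settle within ~10 h at reference
#'   parameters, forbidden ones need ~1e4 h).
#' @param params An [integrase_params()] object.
#' @param t_max Optional override of the integration horizon, hours.
#' @param plateau_tol Relative change over the last time decade below which
#'   the plateau is declared (default 0.005).
#' @return Half-time in hours.
#' @export
half_time <- function(spec, params, t_max = NULL, plateau_tol = 0.005) {
  if (!is.null(t_max)) {
    spec <- experiment_spec(spec$substrate, D_tot = spec$totals$D_tot,
                            I_tot = spec$totals$I_tot,
                            R_tot = spec$totals$R_tot, t_end = t_max,
                            events = spec$events)
  }
  traj <- simulate_time_course(spec, params)
  f <- traj$product_fraction
  t <- traj$t_h
  i_dec <- which(t >= spec$t_end / 10 & t > 0)
  plateau <- f[length(f)]
  if (plateau <= 0)
    stop("no product formed; half-time undefined")
  rel_change <- abs(plateau - f[i_dec[1]]) / max(plateau, .Machine$double.eps)
  if (rel_change > plateau_tol)
    stop(sprintf(paste0("product fraction still changing by %.2g%% over the",
                        " last time decade; increase t_max"),
                 100 * rel_change))
  target <- 0.5 * plateau
  i <- which(f >= target)[1]
  if (i == 1) return(t[1])
  t[i - 1] + (target - f[i - 1]) * (t[i] - t[i - 1]) / (f[i] - f[i - 1])
}

#' Sensitivity scans with thermodynamic closure re-imposed
#'
#' Scans one model constant and reports the plateau recombination extent
#' (and half-time) for each value. Scans over the strand-exchange
#' equilibrium constants `K_r1`/`K_r2` vary the corresponding reverse rate
#' constant and rebuild the parameter set through [integrase_params()], so
#' the compensating change in `K_syn`/`K_synr` demanded by cycle closure is
#' applied automatically. Scans over the rate constants `k_plus_r`,
#' `k_minus_syn`, `k_minus_synr` change forward and reverse rates together,
#' leaving all equilibrium constants untouched.
#'
#' @param which One of `"K_r1"`, `"K_r2"`, `"k_plus_r"`, `"k_minus_syn"`,
#'   `"k_minus_synr"`.
#' @param values Positive values to scan.
#' @param base_free_params Named list of the 8 free constants to start from
#'   (defaults to the reference set).
#' @param spec An [experiment_spec()] defining substrate and totals; its
#'   `t_end` is used as the plateau horizon.
#' @param half_times If `TRUE` (default), also report T0.5 per value.
#' @return Data frame with columns `which`, `value`, `extent`,
#'   optionally `T0.5_h`, plus `cycle_PB_LR` and `cycle_LR_PB` confirming
#'   closure of every scanned set.
#' @export
scan_equilibrium_extent <- function(which = c("K_r1", "K_r2", "k_plus_r",
                                              "k_minus_syn", "k_minus_synr"),
                                    values, base_free_params = NULL, spec,
                                    half_times = TRUE) {
  which <- match.arg(which)
  if (any(values <= 0)) stop("scan values must be positive")
  base <- if (is.null(base_free_params))
    yaml::read_yaml(system.file("extdata", "reference_params.yaml",
                                package = "recombkin"))$parameters
  else as.list(base_free_params)
  rows <- lapply(values, function(v) {
    fp <- base
    if (which == "K_r1") fp$k_minus_r1 <- fp$k_plus_r / v
    else if (which == "K_r2") fp$k_minus_r2 <- fp$k_plus_r / v
    else if (which == "k_plus_r") {
      # scale forward and reverse together: K_r1, K_r2 unchanged
      scale <- v / fp$k_plus_r
      fp$k_plus_r <- v
      fp$k_minus_r1 <- fp$k_minus_r1 * scale
      fp$k_minus_r2 <- fp$k_minus_r2 * scale
    } else fp[[which]] <- v
    p <- do.call(integrase_params, fp)
    ext <- endpoint_extent(
      experiment_spec(spec$substrate, D_tot = spec$totals$D_tot,
                      I_tot = spec$totals$I_tot, R_tot = spec$totals$R_tot,
                      t_end = spec$t_end),
      p, t_read = spec$t_end)
    cyc <- check_thermo_consistency(p)
    out <- data.frame(which = which, value = v, extent = ext,
                      cycle_PB_LR = cyc[[1]], cycle_LR_PB = cyc[[2]])
    if (half_times)
      out$T0.5_h <- half_time(spec, p)
    out
  })
  do.call(rbind, rows)
}
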