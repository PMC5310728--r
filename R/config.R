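#' Unit conversions at the I/O boundary
#'
#' Internally the model works exclusively in micromolar and hours; nanomolar
#' appears only in configs, designs and tables, whose key names carry the
#' unit (`*_nM`, `*_h`).
#'
#' @param x Numeric vector.
#' @return Converted numeric vector.
#' @export
nM_to_uM <- function(x) x / 1e3

#' @rdname nM_to_uM
#' @export
uM_to_nM <- function(x) x * 1e3

.config_blocks <- c("parameters", "experiment", "solver")
.experiment_keys <- c("substrate", "D_tot_nM", "I_tot_nM", "R_tot_nM",
                      "t_end_h", "events")
.solver_keys <- c("method", "rtol", "atol")
.all_param_keys <- c("k_plus_r", "k_minus_r1", "k_minus_r2", "k_plus_syn",
                     "k_minus_syn", "k_plus_synr", "k_minus_synr",
                     "K_bI", "K_bI_i", "K_ir")

#' Load and validate a run configuration
#'
#' Reads a YAML config with blocks `parameters`, `experiment` and `solver`,
#' rejects unknown keys, normalizes units (nM to uM, hours kept) and builds
#' the validated model objects. A `parameters` block with the 8 independent
#' constants is closed thermodynamically; a block giving all 10 constants is
#' checked for consistency instead (an inconsistent set is rejected with the
#' offending cycle products).
#'
#' @param path Path to a YAML file.
#' @return A list of class `run_config` with elements `params`
#'   (`integrase_params`), `spec` (`experiment_spec`, present when the file
#'   has an `experiment` block) and `solver` (list with `method`, `rtol`,
#'   `atol`).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  unknown <- setdiff(names(raw), .config_blocks)
  if (length(unknown))
    stop("unknown config block(s): ", paste(unknown, collapse = ", "))
  if (is.null(raw$parameters)) stop("config lacks a 'parameters' block")

  pk <- names(raw$parameters)
  unknown <- setdiff(pk, .all_param_keys)
  if (length(unknown))
    stop("unknown parameter key(s): ", paste(unknown, collapse = ", "))
  params <- if (all(.all_param_keys %in% pk))
    as_integrase_params(raw$parameters)
  else
    do.call(integrase_params, raw$parameters[intersect(pk,
                                                       free_param_names())])

  spec <- NULL
  if (!is.null(raw$experiment)) {
    ek <- names(raw$experiment)
    unknown <- setdiff(ek, .experiment_keys)
    if (length(unknown))
      stop("unknown experiment key(s): ", paste(unknown, collapse = ", "))
    ex <- raw$experiment
    for (k in c("substrate", "D_tot_nM", "I_tot_nM", "t_end_h"))
      if (is.null(ex[[k]])) stop("experiment block lacks key: ", k)
    events <- NULL
    if (!is.null(ex$events)) {
      events <- lapply(ex$events, function(e) {
        unknown <- setdiff(names(e), c("time_h", "field", "value_nM"))
        if (length(unknown))
          stop("unknown event key(s): ", paste(unknown, collapse = ", "))
        list(time = e$time_h, field = e$field,
             value = nM_to_uM(e$value_nM))
      })
    }
    spec <- experiment_spec(ex$substrate,
                            D_tot = nM_to_uM(ex$D_tot_nM),
                            I_tot = nM_to_uM(ex$I_tot_nM),
                            R_tot = nM_to_uM(ex$R_tot_nM %||% 0),
                            t_end = ex$t_end_h, events = events)
  }

  solver <- list(method = "lsoda", rtol = 1e-8, atol = 1e-12)
  if (!is.null(raw$solver)) {
    unknown <- setdiff(names(raw$solver), .solver_keys)
    if (length(unknown))
      stop("unknown solver key(s): ", paste(unknown, collapse = ", "))
    solver[names(raw$solver)] <- raw$solver
  }
  structure(list(params = params, spec = spec, solver = solver),
            class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a run configuration
#'
#' Inverse of [read_run_config()]: serializes a `run_config` back to YAML
#' with explicit units in the key names, such that reading it back yields
#' an equal configuration.
#'
#' @param config A `run_config` list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  p <- config$params
  out <- list(parameters = p[.all_param_keys])
  if (!is.null(config$spec)) {
    spec <- config$spec
    ex <- list(substrate = spec$substrate,
               D_tot_nM = uM_to_nM(spec$totals$D_tot),
               I_tot_nM = uM_to_nM(spec$totals$I_tot),
               R_tot_nM = uM_to_nM(spec$totals$R_tot),
               t_end_h = spec$t_end)
    if (!is.null(spec$events))
      ex$events <- lapply(spec$events, function(e)
        list(time_h = e$time, field = e$field,
             value_nM = uM_to_nM(e$value)))
    out$experiment <- ex
  }
  out$solver <- config$solver
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

#' Write a tidy table as CSV
#'
#' Canonical tabular output: UTF-8, '.' decimal separator, LF line endings,
#' no row names.
#'
#' @param x Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(x, path) {
  con <- file(path, open = "wb", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.csv(x, con, row.names = FALSE, eol = "\n")
  invisible(path)
}
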