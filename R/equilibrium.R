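#' Conserved total concentrations
#'
#' @param I_tot Total integrase monomer, uM.
#' @param R_tot Total RDF monomer, uM.
#' @param D_tot Total plasmid DNA (PB-containing plus LR-containing), uM.
#' @return A named list of class `recomb_totals`.
#' @export
totals <- function(I_tot, R_tot = 0, D_tot) {
  v <- c(I_tot = I_tot, R_tot = R_tot, D_tot = D_tot)
  if (any(!is.finite(v)) || any(v < 0))
    stop("totals must be finite and non-negative")
  structure(list(I_tot = I_tot, R_tot = R_tot, D_tot = D_tot),
            class = "recomb_totals")
}

#' Free integrase, free RDF and IR complex at solution equilibrium
#'
#' Resolves the fast integrase-RDF association `I + R <-> IR` under the
#' approximation that DNA-bound protein is negligible, so the conservation
#' relations reduce to `I_tot = I + IR` and `R_tot = R + IR`. Eliminating
#' `IR = I*R/K_ir` and `R = R_tot - I_tot + I` gives the quadratic
#' `I^2 + (K_ir + R_tot - I_tot) I - K_ir I_tot = 0`, solved here in the
#' cancellation-free form `I = 2 K_ir I_tot / (b + sqrt(b^2 + 4 K_ir I_tot))`
#' with `b = K_ir + R_tot - I_tot`, which is the root guaranteed to lie in
#' `[0, I_tot]`. Because DNA-bound protein is neglected, the result depends
#' only on the totals and `K_ir`, and is computed once per experiment
#' segment rather than per ODE step.
#'
#' @param totals A [totals()] object (its `D_tot` is not used here).
#' @param params An [integrase_params()] object (only `K_ir` is used).
#' @return Named list with components `I`, `R`, `IR` (uM).
#' @export
free_proteins <- function(totals, params) {
  I_tot <- totals$I_tot
  R_tot <- totals$R_tot
  K_ir <- params$K_ir
  if (I_tot == 0)
    return(list(I = 0, R = R_tot, IR = 0))
  if (R_tot == 0)
    return(list(I = I_tot, R = 0, IR = 0))
  b <- K_ir + R_tot - I_tot
  I <- 2 * K_ir * I_tot / (b + sqrt(b * b + 4 * K_ir * I_tot))
  if (!is.finite(I) || I < 0 || I > I_tot)
    stop("internal error: free-integrase root outside [0, I_tot]")
  IR <- I_tot - I
  R <- R_tot - IR
  list(I = I, R = max(R, 0), IR = IR)
}

# Rapid-equilibrium binding weights. With free integrase I and free
# integrase-RDF complex IR, each fast DNA complex is proportional to its
# free DNA species:
#   PBI   = PB * (I/K_bI)^4          LRI2  = LR * (I/K_bI)^4
#   PBIR2 = PB * (IR/K_bI)^4         LRIR  = LR * (IR/K_bI)^4
#   PBIRi = PB * (I*IR)^2 / K_bI^4   LRIRi = LR * (I*IR)^2 / K_bI_i^4
# den_PB and den_LR are the isotherm denominators that partition the fast
# pools (PB_tot - PBIR1) and (LR_tot - LRI1) among free DNA and complexes.
binding_weights <- function(free, params) {
  phi4 <- (free$I / params$K_bI)^4
  psi4 <- (free$IR / params$K_bI)^4
  mix <- (free$I * free$IR)^2
  mix_PB <- mix / params$K_bI^4
  mix_LR <- mix / params$K_bI_i^4
  list(phi4 = phi4, psi4 = psi4, mix_PB = mix_PB, mix_LR = mix_LR,
       den_PB = 1 + phi4 + psi4 + mix_PB,
       den_LR = 1 + phi4 + psi4 + mix_LR)
}

#' Resolve all 13 species from the slow variables
#'
#' Given the three slow variables (`LRI1`, `PBIR1`, `PB_tot`), the conserved
#' totals and the parameters, computes the full species state under the
#' rapid-equilibrium approximation. The slow complexes `LRI1` and `PBIR1`
#' pass through unchanged; free PB and free LR are obtained by removing the
#' slow complex from each DNA pool and dividing by the binding-isotherm
#' denominator, and every fast complex then follows from its mass-action
#' relation. Free `I`, `R` and `IR` are taken from [free_proteins()] (they
#' depend only on the totals).
#'
#' @param slow Numeric vector `c(LRI1 = , PBIR1 = , PB_tot = )` in uM (names
#'   optional, order fixed).
#' @param totals A [totals()] object.
#' @param params An [integrase_params()] object.
#' @param free Optional precomputed [free_proteins()] result.
#' @return Named numeric vector with the 13 species concentrations (uM):
#'   `I`, `R`, `IR`, `PB`, `LR`, `PBI`, `PBIR1`, `PBIR2`, `PBIRi`, `LRI1`,
#'   `LRI2`, `LRIR`, `LRIRi`.
#' @export
fast_species <- function(slow, totals, params, free = NULL) {
  slow <- as.numeric(slow)
  LRI1 <- slow[1]; PBIR1 <- slow[2]; PB_tot <- slow[3]
  D_tot <- totals$D_tot
  LR_tot <- D_tot - PB_tot
  tol <- 1e-9 * max(D_tot, 1e-12)
  if (min(LRI1, PBIR1, PB_tot) < -tol || PB_tot > D_tot + tol)
    stop("invalid slow state: negative concentration or PB_tot > D_tot")
  if (PBIR1 > PB_tot + tol)
    stop("invalid slow state: PBIR1 exceeds total PB")
  if (LRI1 > LR_tot + tol)
    stop("invalid slow state: LRI1 exceeds total LR")
  if (is.null(free)) free <- free_proteins(totals, params)
  w <- binding_weights(free, params)
  PB <- max(PB_tot - PBIR1, 0) / w$den_PB
  LR <- max(LR_tot - LRI1, 0) / w$den_LR
  c(I = free$I, R = free$R, IR = free$IR,
    PB = PB, LR = LR,
    PBI = PB * w$phi4, PBIR1 = PBIR1, PBIR2 = PB * w$psi4,
    PBIRi = PB * w$mix_PB,
    LRI1 = LRI1, LRI2 = LR * w$phi4, LRIR = LR * w$psi4,
    LRIRi = LR * w$mix_LR)
}

# species bookkeeping shared by the reduced and full models
.pb_species <- c("PB", "PBI", "PBIR1", "PBIR2", "PBIRi")
.lr_species <- c("LR", "LRI1", "LRI2", "LRIR", "LRIRi")

#' Sum DNA pools of a species state
#'
#' @param species Named vector as returned by [fast_species()].
#' @return Named vector `c(PB_tot = , LR_tot = )` in uM.
#' @export
dna_pools <- function(species) {
  c(PB_tot = sum(species[.pb_species]), LR_tot = sum(species[.lr_species]))
}

#' Protein bound in DNA complexes
#'
#' Accounts integrase and RDF monomers sequestered in DNA complexes: every
#' synaptic complex carries 4 integrase protomers; RDF-containing productive
#' complexes carry 4 RDF, while the unproductive complexes `PBIRi`/`LRIRi`
#' carry 2 RDF (and 4 integrase).
#'
#' @param species Named vector as returned by [fast_species()].
#' @return Named vector `c(I_bound = , R_bound = )` in uM of monomer.
#' @export
bound_protein <- function(species) {
  four_I <- c("PBI", "PBIR1", "PBIR2", "PBIRi", "LRI1", "LRI2", "LRIR",
              "LRIRi")
  four_R <- c("PBIR1", "PBIR2", "LRIR")
  two_R <- c("PBIRi", "LRIRi")
  c(I_bound = 4 * sum(species[four_I]),
    R_bound = 4 * sum(species[four_R]) + 2 * sum(species[two_R]))
}
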