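# recombkin

Kinetic modelling of directional DNA site-specific recombination by serine
integrases.

Serine integrases (the phiC31 enzyme is the reference system here)
recombine phage *attP* with host *attB* sites to give *attL*/*attR*, and
only reverse that reaction when their recombination directionality factor
(RDF) is present — even though substrates and products are isoenergetic
and no cofactor is consumed. `recombkin` implements a minimal kinetic
model of this directionality for an intramolecular plasmid substrate: fast
protein–DNA binding is resolved by a rapid-equilibrium reduction, leaving
three slow ODEs (in [LRI1], [PBIR1] and total PB) driven by the reversible
strand-exchange steps r1, r2 and the very slow synaptic-conformation steps
syn, synr. Directionality is kinetic trapping: the substrate of each
"forbidden" reaction is captured in a blocked complex (LRI2 or PBIR2) that
reaches the productive conformer only on a timescale of days.

The model is thermodynamically closed by Wegscheider's condition — the
product of equilibrium constants around each reaction cycle is 1. With the
binding steps sharing one dissociation constant K_bI this reduces to

    K_syn = 1 / K_r1,     K_synr = 1 / K_r2,

so of the 10 rate/dissociation constants only 8 are free; the constructor
derives the rest, and the fitting layer can never visit an inconsistent
set. An unreduced 13-species mass-action network ships alongside as an
independent oracle: the reduced model is its fast-binding limit, and the
package tests that the deviation in product fraction shrinks below 0.02 as
binding accelerates.

For whom: anyone modelling serine-integrase reaction kinetics or designing
integrase-based genetic switches, and anyone who wants a compact worked
example of rapid-equilibrium reduction with detailed-balance constraints.

## Worked example

```r
library(recombkin)
p <- reference_params()
p
#> Thermodynamically closed integrase recombination parameters
#>   (concentrations in uM, times in hours)
#>   rate constants [1/h]: k_plus_r = 5, k_minus_r1 = 0.55, k_minus_r2 = 1.35,
#>     k_plus_syn = 0.00022, k_minus_syn = 0.002, k_plus_synr = 0.0027, k_minus_synr = 0.01
#>   dissociation constants [uM]: K_bI = 0.1, K_bI_i = 0.02, K_ir = 0.01
#>   equilibrium constants: K_r1 = 9.091, K_r2 = 3.704, K_syn = 0.11, K_synr = 0.27
#>   cycle products: 1 (PB->LR), 1 (LR->PB)
```

A 3-hour endpoint titration on PB substrate (10 nM plasmid), in nM at the
interface and µM internally:

```r
titration_grid("PB", 0.01, c(0.05, 0.1, 0.2, 0.4), c(0, 0.4, 0.8), p)
#>    substrate I_tot_nM R_tot_nM t_h product_fraction
#> 1         PB       50        0   3          0.32079
#> 2         PB      100        0   3          0.81966
#> 3         PB      200        0   3          0.89541
#> 4         PB      400        0   3          0.90060
#> 8         PB      400      400   3          0.02488
#> 12        PB      400      800   3          0.00743
```

Read: without RDF the reaction saturates near 90% once integrase exceeds
~200 nM; RDF at or above the integrase concentration collapses it to a few
percent (the DNA is diverted into the blocked PBIR2 complex).

The model's signature prediction — add RDF one hour into an RDF-free P×B
reaction and the DNA returns almost quantitatively to PB, overshooting the
~73% ceiling of the one-pot L×R(+RDF) reaction:

```r
sw <- rdf_switch(0.01, 0.4, 0.8, t_switch = 1, t_end = 10, params = p)
sw$max_PB_fraction
#> [1] 0.975
```

Fitting the four identifiable constants back from a synthetic noisy
titration grid (σ = 0.02):

```r
d <- generate_synthetic_endpoints(p, noise_sigma = 0.02, seed = 42)
fit_endpoints(d, which_free = c("k_minus_r1", "k_minus_r2", "K_bI", "K_ir"),
              n_starts = 1)
#> Endpoint-titration fit of integrase recombination constants
#>   50 observations, weighted SSR = 52.74
#>   k_minus_r1    = 0.5677  [0.319, 1.01]
#>   k_minus_r2    = 1.284  [0.722, 2.28]
#>   K_bI          = 0.102  [0.0574, 0.181]
#>   K_ir          = 0.01062  [0.00597, 0.0189]
```

See `vignettes/integrase-kinetics.Rmd` for the model derivation, parameter
rationale, numerical choices and limitations. A thin command-line wrapper
(`inst/cli/recombkin-cli.R`) exposes the protocols as subcommands
(`simulate`, `titrate`, `switch`, `scan`, `validate`, `synth`, `fit`).

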