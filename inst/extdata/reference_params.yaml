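# Reference constants for phiC31 integrase (I) + RDF gp3 (R), version 1.
# Units: rate constants 1/hour, dissociation constants micromolar.
# Only the 8 independent constants are stored; K_syn/K_synr (hence
# k_plus_syn/k_plus_synr) are derived from Wegscheider closure of the two
# reaction cycles when the set is loaded.
parameters:
  k_plus_r: 5.0        # shared forward rate of strand-exchange steps r1, r2
  k_minus_r1: 0.55     # reverse of r1 (LRI1 -> PBI); K_r1 = k_plus_r/k_minus_r1
  k_minus_r2: 1.35     # reverse of r2 (PBIR1 -> LRIR)
  k_minus_syn: 0.002   # very slow LRI2 -> LRI1 conversion (days scale)
  k_minus_synr: 0.01   # very slow PBIR2 -> PBIR1 conversion
  K_bI: 0.1            # shared protein-DNA dissociation constant (steps b1-b4, PBIRi)
  K_bI_i: 0.02         # unproductive LRIRi complex; must be < K_bI
  K_ir: 0.01           # integrase-RDF 1:1 solution complex
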