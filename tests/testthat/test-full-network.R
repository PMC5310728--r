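test_that("network stoichiometry matches the complex compositions", {
  p <- reference_params()
  net <- full_network(p)
  get_rx <- function(nm) which(net$reactions == nm)
  # synaptic binding consumes 4 protein units
  expect_equal(unname(net$Vr["I", get_rx("b1")]), 4)
  expect_equal(unname(net$Vr["IR", get_rx("b3")]), 4)
  # unproductive complexes consume 2 I + 2 IR = 4 integrase + 2 RDF
  expect_equal(unname(net$Vr["I", get_rx("bi_PB")]), 2)
  expect_equal(unname(net$Vr["IR", get_rx("bi_PB")]), 2)
  expect_equal(unname(net$Vr["I", get_rx("bi_LR")]), 2)
  expect_equal(unname(net$Vr["IR", get_rx("bi_LR")]), 2)
  # every fast step's k_off/k_on reproduces its dissociation constant
  K <- net$kb / net$kf
  expect_equal(K[get_rx("ir")], p$K_ir)
  expect_equal(K[get_rx("b1")], p$K_bI^4)
  expect_equal(K[get_rx("bi_LR")], p$K_bI_i^4)
  # slow steps carry the model rate constants unchanged
  expect_equal(net$kf[get_rx("r1")], p$k_plus_r)
  expect_equal(net$kb[get_rx("syn")], p$k_minus_syn)
})

test_that("network cycle products are 1 for a closed parameter set", {
  p <- reference_params()
  expect_equal(unname(network_cycle_products(full_network(p))), c(1, 1),
               tolerance = 1e-12)
})

test_that("no integrase leaves the network inert", {
  p <- reference_params()
  net <- full_network(p, k_fast = 1e3)
  tr <- simulate_full_network(net, experiment_spec(
    "PB", D_tot = 0.01, I_tot = 0, R_tot = 0.8, t_end = 3))
  expect_true(all(tr$product_fraction == 0))
  expect_equal(tr$PB[nrow(tr)], 0.01, tolerance = 1e-10)
})

test_that("equilibria do not depend on the fast-step rate magnitude", {
  p <- reference_params()
  gl <- c(0, 10^seq(-3, 4, length.out = 80))
  spec <- experiment_spec("LR", D_tot = 0.01, I_tot = 0.4, R_tot = 0.8,
                          t_end = 1e4, output_grid = gl)
  a <- simulate_full_network(full_network(p, k_fast = 50), spec)
  b <- simulate_full_network(full_network(p, k_fast = 500), spec)
  ea <- as.numeric(a[nrow(a), species_names])
  eb <- as.numeric(b[nrow(b), species_names])
  expect_lt(max(abs(ea - eb) / pmax(abs(ea), 1e-12)), 1e-3)
})

test_that("full network conserves DNA and protein exactly", {
  p <- reference_params()
  spec <- experiment_spec("LR", D_tot = 0.01, I_tot = 0.4, R_tot = 0.8,
                          t_end = 10)
  tr <- simulate_full_network(full_network(p, 1e3), spec)
  dna <- rowSums(as.matrix(tr[, c(pb_names, lr_names)]))
  expect_lt(max(abs(dna - 0.01)), 1e-6 * 0.01)
  Ibound <- 4 * rowSums(as.matrix(tr[, c("PBI", "PBIR1", "PBIR2", "PBIRi",
                                         "LRI1", "LRI2", "LRIR", "LRIRi")]))
  Itot <- tr$I + tr$IR + Ibound
  Rtot <- tr$R + tr$IR +
    4 * rowSums(as.matrix(tr[, c("PBIR1", "PBIR2", "LRIR")])) +
    2 * rowSums(as.matrix(tr[, c("PBIRi", "LRIRi")]))
  expect_lt(max(abs(Itot - 0.4)), 1e-6 * 0.4)
  expect_lt(max(abs(Rtot - 0.8)), 1e-6 * 0.8)
  # protein sequestered on DNA can never exceed 4 per plasmid
  expect_lt(max(Ibound), 4 * 0.01 * (1 + 1e-9))
})

test_that("full-network equilibrium is independent of the starting
           substrate (detailed balance)", {
  p <- reference_params()
  gl <- c(0, 10^seq(-3, 5, length.out = 80))
  mk <- function(sub) experiment_spec(sub, D_tot = 0.01, I_tot = 0.4,
                                      R_tot = 0.8, t_end = 1e5,
                                      output_grid = gl)
  net <- full_network(p, k_fast = 100)
  a <- simulate_full_network(net, mk("PB"))
  b <- simulate_full_network(net, mk("LR"))
  ea <- as.numeric(a[nrow(a), species_names])
  eb <- as.numeric(b[nrow(b), species_names])
  expect_lt(max(abs(ea - eb) / pmax(abs(ea), 1e-12)), 1e-3)
})

test_that("free integrase approximation error is bounded by sequestration", {
  p <- reference_params()
  for (cond in list(c(I = 0.4, R = 0.8), c(I = 0.4, R = 0))) {
    spec <- experiment_spec("LR", D_tot = 0.01, I_tot = cond[["I"]],
                            R_tot = cond[["R"]], t_end = 10)
    tr <- simulate_full_network(full_network(p, 1e4), spec)
    fp <- free_proteins(spec$totals, p)
    rel_dev <- abs(tr$I[nrow(tr)] - fp$I) / max(fp$I, 1e-12)
    expect_lt(rel_dev, sequestered_integrase_bound(0.01, cond[["I"]]) * 1.05)
  }
  # once sequestration can claim only a few percent of the pool, free
  # integrase agrees within 5%
  spec <- experiment_spec("LR", D_tot = 0.01, I_tot = 1.6, R_tot = 3.2,
                          t_end = 10)
  tr <- simulate_full_network(full_network(p, 1e4), spec)
  fp <- free_proteins(spec$totals, p)
  expect_lt(abs(tr$I[nrow(tr)] - fp$I) / fp$I, 0.05)
})

test_that("the reduced model converges to the full network as binding gets
           fast, monotonically", {
  p <- reference_params()
  spec <- experiment_spec("LR", D_tot = 0.01, I_tot = 0.4, R_tot = 0.8,
                          t_end = 10)
  cmp <- compare_reduced_full(spec, p, k_fast_values = c(1e2, 1e3, 1e4))
  expect_true(all(diff(cmp$max_abs_deviation) < 0))
  expect_lt(cmp$max_abs_deviation[3], 0.02)
})
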