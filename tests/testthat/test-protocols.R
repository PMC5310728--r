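test_that("titration grid reproduces the directional structure", {
  p <- reference_params()
  I_vals <- c(0.025, 0.05, 0.1, 0.2, 0.4)
  pb <- titration_grid("PB", 0.01, I_vals, c(0, 0.4, 0.8), p)
  lr <- titration_grid("LR", 0.01, I_vals, c(0, 0.4, 0.8), p)
  # integrase titration without RDF: non-decreasing up to saturation
  f0 <- pb$product_fraction[pb$R_tot_nM == 0]
  expect_true(all(diff(f0) > -1e-9))
  expect_gt(max(f0), 0.85)
  # forbidden LxR(-RDF) row is near zero
  expect_lt(max(lr$product_fraction[lr$R_tot_nM == 0]), 0.01)
  # RDF at or above integrase strongly inhibits PxB
  expect_lt(max(pb$product_fraction[pb$R_tot_nM >= pb$I_tot_nM]), 0.06)
  # ...and stimulates LxR at saturating protein
  expect_gt(lr$product_fraction[lr$I_tot_nM == 400 & lr$R_tot_nM == 800],
            0.5)
})

test_that("endpoint extent switches sharply as RDF crosses integrase", {
  p <- reference_params()
  I <- 0.4
  below <- 0.5 * I; above <- 2 * I
  pb_lo <- endpoint_extent(ref_spec("PB", R_tot = below), p)
  pb_hi <- endpoint_extent(ref_spec("PB", R_tot = above), p)
  lr_lo <- endpoint_extent(ref_spec("LR", R_tot = below), p)
  lr_hi <- endpoint_extent(ref_spec("LR", R_tot = above), p)
  expect_gt(pb_lo - pb_hi, 0.5)   # PxB collapses
  expect_gt(lr_hi - lr_lo, 0.5)   # LxR switches on
})

test_that("titration tables round-trip through the canonical CSV writer", {
  p <- reference_params()
  tab <- titration_grid("PB", 0.01, c(0.1, 0.4), c(0, 0.8), p)
  path <- tempfile(fileext = ".csv")
  write_table_csv(tab, path)
  back <- utils::read.csv(path, stringsAsFactors = FALSE)
  expect_equal(back$product_fraction, tab$product_fraction,
               tolerance = 1e-12)
  expect_identical(names(back), names(tab))
})

test_that("delayed RDF addition overshoots the one-pot LxR(+RDF) ceiling", {
  p <- reference_params()
  sw <- rdf_switch(0.01, 0.4, 0.8, t_switch = 1, t_end = 10, params = p)
  lr <- simulate_time_course(ref_spec("LR", R_tot = 0.8, t_end = 10), p)
  expect_gt(sw$max_PB_fraction, max(lr$product_fraction))
  expect_gt(sw$max_PB_fraction, 0.9)
  expect_error(rdf_switch(0.01, 0.4, 0.8, t_switch = 10, t_end = 10,
                          params = p), "t_switch")
})

test_that("a null switch event reproduces the plain RDF-free run", {
  p <- reference_params()
  sw <- rdf_switch(0.01, 0.4, R_after = 0, t_switch = 1, t_end = 3,
                   params = p)
  plain <- simulate_time_course(
    experiment_spec("PB", D_tot = 0.01, I_tot = 0.4, R_tot = 0, t_end = 3,
                    output_grid = sw$trajectory$t_h), p)
  for (nm in species_names)
    expect_equal(sw$trajectory[[nm]], plain[[nm]], tolerance = 1e-8)
})

test_that("half-time matches the closed-form single-exponential limit", {
  p <- reference_params()
  # saturating integrase, no RDF: du/dt = -(k_+r x1 + k_-r1) u + k_-r1 D,
  # an exact single exponential, so T0.5 = ln 2 / rate
  fp <- free_proteins(totals(0.4, 0, 0.01), p)
  phi4 <- (fp$I / p$K_bI)^4
  x1 <- phi4 / (1 + phi4)
  rate <- p$k_plus_r * x1 + p$k_minus_r1
  t50 <- half_time(ref_spec(t_end = 30), p)
  expect_equal(t50, log(2) / rate, tolerance = 0.02)
})

test_that("half-time errors when no plateau is reached", {
  p <- reference_params()
  expect_error(half_time(ref_spec("LR", R_tot = 0, t_end = 10), p),
               "t_max")
})

test_that("allowed half-times shorten as strand exchange accelerates", {
  p0 <- yaml::read_yaml(system.file("extdata", "reference_params.yaml",
                                    package = "recombkin"))$parameters
  spec <- ref_spec(t_end = 30)
  tab <- scan_equilibrium_extent("k_plus_r",
                                 10^seq(0.5, 2, length.out = 10), p0, spec)
  expect_true(all(diff(tab$T0.5_h) < 0))
  # equilibrium constants untouched by a rate-constant scan: extent stable
  expect_lt(diff(range(tab$extent)), 0.02)
})

test_that("forbidden half-times are controlled by the slow step", {
  p0 <- yaml::read_yaml(system.file("extdata", "reference_params.yaml",
                                    package = "recombkin"))$parameters
  spec <- experiment_spec("LR", D_tot = 0.01, I_tot = 0.4, R_tot = 0,
                          t_end = 1e5)
  tab <- scan_equilibrium_extent("k_minus_syn", c(0.002, 0.008, 0.032),
                                 p0, spec)
  expect_true(all(diff(tab$T0.5_h) < 0))
  expect_gt(tab$T0.5_h[1], 24)  # days scale at the reference value
})

test_that("equilibrium-extent scans re-impose cycle closure", {
  p0 <- yaml::read_yaml(system.file("extdata", "reference_params.yaml",
                                    package = "recombkin"))$parameters
  spec <- ref_spec(t_end = 10)
  tab <- scan_equilibrium_extent("K_r1", c(0.1, 1, 9, 90), p0, spec,
                                 half_times = FALSE)
  expect_true(all(abs(tab$cycle_PB_LR - 1) < 1e-12))
  expect_true(all(abs(tab$cycle_LR_PB - 1) < 1e-12))
  expect_true(all(diff(tab$extent) > 0))
  expect_lt(tab$extent[1], 0.15)       # K_r1 -> 0: no conversion
  expect_lt(tab$extent[4], 1)          # saturating but bounded by partitioning
  expect_gt(tab$extent[4], 0.95)
})
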