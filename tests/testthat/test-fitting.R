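test_that("synthetic endpoint data are reproducible and correctly scaled", {
  p <- reference_params()
  d0 <- generate_synthetic_endpoints(p, noise_sigma = 0, seed = 1)
  expect_equal(d0$observed_fraction, predict_endpoints_oracle(p, d0),
               tolerance = 1e-8)
  d1 <- generate_synthetic_endpoints(p, noise_sigma = 0.02, seed = 99)
  d2 <- generate_synthetic_endpoints(p, noise_sigma = 0.02, seed = 99)
  expect_identical(d1$observed_fraction, d2$observed_fraction)
  d3 <- generate_synthetic_endpoints(p, noise_sigma = 0.02, seed = 100)
  expect_false(identical(d1$observed_fraction, d3$observed_fraction))
  expect_true(all(d1$observed_fraction >= 0 & d1$observed_fraction <= 1))
})

test_that("generator noise has the declared scale", {
  p <- reference_params()
  # pool residuals over several seeds: about 95% within +/- 2 sigma
  res <- unlist(lapply(1:8, function(s) {
    d <- generate_synthetic_endpoints(p, noise_sigma = 0.02, seed = s)
    d$observed_fraction - generate_synthetic_endpoints(
      p, noise_sigma = 0, seed = s)$observed_fraction
  }))
  expect_gt(mean(abs(res) <= 0.04), 0.92)
  expect_lt(mean(abs(res) <= 0.04), 0.995)
})

test_that("noiseless data are recovered from a perturbed start", {
  p <- reference_params()
  d <- generate_synthetic_endpoints(p, noise_sigma = 0, seed = 1)
  start <- as.list(unlist(yaml::read_yaml(system.file(
    "extdata", "reference_params.yaml", package = "recombkin"))$parameters))
  wf <- c("k_minus_r1", "k_minus_r2", "K_bI", "K_ir")
  start[wf] <- lapply(start[wf], function(v) 3 * v)
  fit <- fit_endpoints(d, start = start, which_free = wf, n_starts = 1)
  expect_lt(fit$ssr, 1e-4)
  for (nm in wf)
    expect_equal(unname(fit$par[[nm]]), unclass(p)[[nm]], tolerance = 0.05)
  # the fitted set is thermodynamically closed
  expect_equal(unname(check_thermo_consistency(fit$params)), c(1, 1),
               tolerance = 1e-12)
})

test_that("the search space itself is thermodynamically closed", {
  # any candidate the objective can visit is rebuilt through the closure
  # constructor, so even a deliberately inconsistent start cannot introduce
  # an open cycle
  p <- reference_params()
  d <- generate_synthetic_endpoints(p, noise_sigma = 0.02, seed = 5)
  fit <- fit_endpoints(d, which_free = c("k_minus_r1", "K_bI"),
                       n_starts = 2, maxit = 30)
  expect_equal(unname(check_thermo_consistency(fit$params)), c(1, 1),
               tolerance = 1e-12)
})

test_that("without forbidden-reaction data the slow constant is bounded,
           not estimated", {
  p <- reference_params()
  # allowed conditions only: PxB without RDF, LxR with RDF at 2x integrase
  design <- rbind(
    titration_design(I_nM = c(50, 100, 200, 400), R_nM = 0,
                     substrates = "PB"),
    titration_design(I_nM = c(50, 100, 200, 400), R_nM = 800,
                     substrates = "LR"))
  d <- generate_synthetic_endpoints(p, design, noise_sigma = 0.02, seed = 3)
  fit <- fit_endpoints(d, which_free = c("k_minus_r1", "k_minus_syn"),
                       n_starts = 1)
  expect_identical(fit$profile$k_minus_syn$type, "upper_bound")
  expect_true(is.na(fit$profile$k_minus_syn$lower))
  expect_false(is.na(fit$profile$k_minus_syn$upper))
  # while the strand-exchange constant is identified by the same data
  expect_identical(fit$profile$k_minus_r1$type, "identified")
})

test_that("fit object methods are coherent", {
  p <- reference_params()
  d <- generate_synthetic_endpoints(p, noise_sigma = 0.02, seed = 7)
  fit <- fit_endpoints(d, which_free = c("k_minus_r1", "K_bI"),
                       n_starts = 1, maxit = 60)
  expect_named(coef(fit), c("k_minus_r1", "K_bI"))
  expect_equal(unname(predict(fit)), fit$predicted)
  expect_equal(residuals(fit, type = "raw"),
               d$observed_fraction - fit$predicted)
  expect_equal(fit$ssr, sum(residuals(fit)^2), tolerance = 1e-10)
  sims <- simulate(fit, nsim = 2, seed = 4)
  expect_length(sims, 2)
  expect_s3_class(sims[[1]], "endpoint_data")
  expect_output(print(fit), "weighted SSR")
})

test_that("recovery error shrinks as measurement noise vanishes", {
  p <- reference_params()
  truth <- unclass(p)
  wf <- c("k_minus_r1", "k_minus_r2", "K_bI", "K_ir")
  start <- as.list(unlist(yaml::read_yaml(system.file(
    "extdata", "reference_params.yaml", package = "recombkin"))$parameters))
  start[wf] <- lapply(start[wf], function(v) 3 * v)
  design <- titration_design(I_nM = c(50, 100, 200, 400),
                             R_nM = c(0, 200, 400, 800))
  seeds <- 1:6
  med_err <- vapply(c(0.05, 0.02, 0), function(sg) {
    errs <- vapply(seeds, function(s) {
      d <- generate_synthetic_endpoints(p, design, noise_sigma = sg,
                                        seed = s)
      fit <- fit_endpoints(d, start = start, which_free = wf, n_starts = 1,
                           maxit = 80)
      mean(abs(unlist(fit$par[wf]) - unlist(truth[wf])) / unlist(truth[wf]))
    }, numeric(1))
    median(errs)
  }, numeric(1))
  expect_true(all(diff(med_err) <= 1e-8))
})
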