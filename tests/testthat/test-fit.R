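make_clean_ds <- function(params, seed = 1, observable = "relative_mrna") {
  generate_timecourse(base_spec, params, observable = observable,
                      noise = noise_model(sigma = 0), seed = seed)
}

test_that("residuals vanish at the generating parameters", {
  ds <- make_clean_ds(FX$RNAiMAX$parameters)
  r <- fit_residuals(ds, base_spec, FX$RNAiMAX$parameters,
                     free = c("k1", "k2", "k4"),
                     values = FX$RNAiMAX$parameters$values[c("k1", "k2",
                                                             "k4")])
  expect_lt(max(abs(r)), 1e-6)
})

test_that("the normalization anchor at t = 0 carries no information", {
  ds <- timecourse_dataset(
    data.frame(time_hr = c(0, 1, 2, 3), value = c(1, 1, 1, 1)),
    observable = "relative_mrna")
  for (k2 in c(1e-4, 0.01, 0.5)) {
    r <- fit_residuals(ds, base_spec, baseline, free = "k2", values = k2)
    expect_equal(r[1], 0, tolerance = 1e-12)
  }
})

test_that("the objective is locally minimized at the generating value", {
  ds <- generate_timecourse(base_spec, FX$LNP05$parameters, seed = 11)
  ssr <- function(k2) sum(fit_residuals(ds, base_spec,
                                        FX$LNP05$parameters, "k2", k2)^2)
  # +10% perturbation from truth strictly increases the misfit
  expect_gt(ssr(0.002 * 1.1), ssr(0.002))
  expect_gt(ssr(0.002 * 0.9), ssr(0.002))
})

test_that("noise-free data recover the escape rate essentially exactly", {
  ds <- make_clean_ds(FX$LNP05$parameters)
  fit <- fit_vehicle(ds, base_spec, FX$LNP05$parameters, free = "k2",
                     n_starts = 8, seed = 3)
  expect_lt(abs(fit$estimates[["k2"]] - 0.002) / 0.002, 1e-3)
  expect_lt(fit$objective, 1e-10)
})

test_that("fits are deterministic and internally consistent", {
  ds <- generate_timecourse(base_spec, FX$RNAiMAX$parameters, seed = 5)
  f1 <- fit_vehicle(ds, base_spec, FX$RNAiMAX$parameters, free = "k2",
                    n_starts = 6, seed = 9)
  f2 <- fit_vehicle(ds, base_spec, FX$RNAiMAX$parameters, free = "k2",
                    n_starts = 6, seed = 9)
  expect_identical(f1$estimates, f2$estimates)
  expect_identical(f1$starts, f2$starts)
  # objective equals a fresh residual recomputation at the estimate
  r <- fit_residuals(ds, base_spec, FX$RNAiMAX$parameters, f1$free,
                     f1$estimates)
  expect_equal(f1$objective, sum(r^2), tolerance = 1e-10)
  # estimates within bounds; objective no worse than any start
  expect_true(all(f1$estimates >= vapply(f1$bounds, `[`, numeric(1), 1)))
  expect_true(all(f1$estimates <= vapply(f1$bounds, `[`, numeric(1), 2)))
  expect_true(all(f1$objective <= f1$starts$objective_start + 1e-12))
})

test_that("fitting demands at least four distinct time points", {
  ds <- timecourse_dataset(
    data.frame(time_hr = c(0, 5, 21), value = c(1, 0.9, 0.8)),
    observable = "relative_mrna")
  expect_error(fit_vehicle(ds, base_spec, baseline, free = "k2"),
               "4 distinct")
})

test_that("joint fits on knockdown-only data flag weak identifiability", {
  ds <- generate_timecourse(base_spec, FX$RNAiMAX$parameters, seed = 21)
  expect_warning(
    fit_vehicle(ds, base_spec, FX$RNAiMAX$parameters,
                free = c("k1", "k2", "k4"), n_starts = 4, seed = 21),
    "identifiability")
})

test_that("vehicle and cargo constants transfer into a predictive set", {
  ds <- make_clean_ds(FX$LNP05$parameters)
  veh <- fit_vehicle(ds, base_spec, FX$LNP05$parameters, free = "k2",
                     n_starts = 4, seed = 2)
  crg <- suppressWarnings(
    fit_vehicle(ds, base_spec, FX$LNP05$parameters, free = "k4",
                n_starts = 4, seed = 2))
  combined <- transfer_parameters(veh, crg, FX$LNP05$parameters)
  expect_s3_class(combined, "lnp_parameters")
  expect_equal(combined$values[["k2"]], veh$estimates[["k2"]])
  expect_equal(combined$values[["k4"]], crg$estimates[["k4"]])
  expect_identical(combined$provenance[["k2"]], "fitted")
  # a transferred set simulates without further fitting
  sim <- simulate_model(base_spec, combined)
  expect_s3_class(sim, "lnp_simulation")
  # identity: fits that recover the baseline return the baseline
  expect_equal(combined$values[["k2"]], 0.002, tolerance = 1e-3)
})

test_that("two cargoes under one vehicle differ only through k4", {
  # swapping k4 between two parameter sets built from the same vehicle
  # reproduces each other's knockdown exactly
  cargo_a <- update_parameters(FX$LNP05$parameters, k4 = 2e-6)
  cargo_b <- update_parameters(FX$LNP05$parameters, k4 = 5e-7)
  swapped <- update_parameters(cargo_b, k4 = 2e-6)
  kd_a <- knockdown_timecourse(simulate_model(base_spec, cargo_a))
  kd_s <- knockdown_timecourse(simulate_model(base_spec, swapped))
  expect_identical(kd_a$value, kd_s$value)
})
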