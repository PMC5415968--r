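test_that("sensitivity to transcription matches the closed form when no
          siRNA is present", {
  # with zero dose the mRNA subsystem is linear:
  # dM/dk8 = (1 - exp(-k9 t)) / k9
  spec0 <- experiment_spec(dose_nM = 0)
  tt <- seq(0, 24, 1)
  sens <- forward_sensitivities(spec0, baseline, times = tt,
                                targets = c("k8", "k9"))
  k9 <- baseline$values[["k9"]]
  expect_equal(sens$raw[, "k8"], (1 - exp(-k9 * tt)) / k9,
               tolerance = 1e-6)
  # all sensitivities start at zero
  full <- forward_sensitivities(base_spec, baseline, times = seq(0, 2, 1))
  expect_true(all(full$raw[1, ] == 0))
  expect_true(all(full$normalized[1, ] == 0))
})

test_that("forward and finite-difference sensitivities agree to <1%", {
  tt <- seq(0, 24, 2)
  fw <- forward_sensitivities(base_spec, baseline, times = tt,
                              rtol = 1e-10, atol = 1e-9)
  fd <- finite_difference_sensitivities(base_spec, baseline, times = tt)
  for (p in colnames(fw$raw)) {
    sc <- max(abs(fw$raw[, p]))
    idx <- abs(fw$raw[, p]) > 1e-9 * sc
    expect_lt(max(abs(fd$raw[idx, p] - fw$raw[idx, p]) /
                    abs(fw$raw[idx, p])), 0.01, label = p)
  }
})

test_that("sensitivities honor the escape-onset delay", {
  # before onset nothing has escaped, so silencing-side sensitivities are 0
  tt <- seq(0, 6, 0.25)
  sens <- forward_sensitivities(base_spec, FX$LNP05$parameters, times = tt,
                                targets = c("k2", "k4"))
  pre <- tt < 1.75
  expect_true(all(sens$raw[pre, "k2"] == 0))
  expect_true(all(sens$raw[pre, "k4"] == 0))
  expect_true(any(sens$raw[!pre, "k2"] != 0))
})

test_that("escape rate dominates the parameter ranking", {
  sens <- forward_sensitivities(base_spec, baseline)
  rk <- rank_parameters(sens)
  expect_setequal(rk$parameter, paste0("k", 1:9))
  expect_identical(rk$parameter[1], "k2")
  # "by far": clear margin over the runner-up
  expect_gt(rk$score[1], 1.5 * rk$score[2])
  # uptake and loading carry the next-largest scores
  expect_true(all(c("k1", "k4") %in% rk$parameter[2:4]))
})

test_that("ranking is stable under tolerances and baseline perturbation", {
  top1 <- function(params, ...) {
    rank_parameters(forward_sensitivities(base_spec, params,
                                          times = seq(0, 24, 0.5),
                                          ...))$parameter[1]
  }
  expect_identical(top1(baseline, rtol = 5e-9, atol = 5e-7), "k2")
  set.seed(42)
  for (i in 1:3) {
    v <- as.list(baseline$values[1:9] * stats::runif(9, 0.9, 1.1))
    pp <- do.call(update_parameters, c(list(params = baseline), v))
    expect_identical(top1(pp), "k2")
  }
})

test_that("a parameter without leverage scores zero and ranks last", {
  # with zero dose nothing intracellular moves: delivery-side parameters
  # carry no sensitivity at all
  sens <- forward_sensitivities(experiment_spec(dose_nM = 0), baseline)
  rk <- rank_parameters(sens)
  expect_equal(rk$score[rk$parameter == "k1"], 0)
  expect_true(rk$parameter[1] %in% c("k8", "k9"))
  # doubling the horizon never decreases a score
  s12 <- rank_parameters(forward_sensitivities(base_spec, baseline,
                                               horizon = 12,
                                               times = seq(0, 12, 0.1)))
  s24 <- rank_parameters(forward_sensitivities(base_spec, baseline,
                                               horizon = 24))
  m <- merge(s12, s24, by = "parameter")
  expect_true(all(m$score.y >= m$score.x - 1e-12))
})

test_that("single-point scan at the baseline reproduces the baseline", {
  sc <- parameter_scan(base_spec, baseline, "k2",
                       baseline$values[["k2"]])
  ref <- knockdown_timecourse(simulate_model(base_spec, baseline))
  expect_identical(sc$table$relative_mrna_end, ref$value[nrow(ref)])
  expect_identical(sc$curves[[1]]$value, ref$value)
})

test_that("scan endpoints are monotone in uptake and reproducible", {
  grid <- scan_grid(0.005, 5, 9)
  sc1 <- parameter_scan(base_spec, baseline, "k1", grid)
  sc2 <- parameter_scan(base_spec, baseline, "k1", grid)
  expect_identical(sc1$table, sc2$table)
  expect_true(all(diff(sc1$table$relative_mrna_end) <= 1e-9))
})

test_that("escape scan reaches deeper knockdown than uptake or loading
          scans", {
  pre <- scan_presets(base_spec)
  mins <- vapply(names(pre), function(p)
    min(parameter_scan(base_spec, baseline, p,
                       pre[[p]])$table$relative_mrna_end), numeric(1))
  expect_lt(mins[["k2"]], mins[["k1"]])
  expect_lt(mins[["k2"]], mins[["k4"]])
})
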