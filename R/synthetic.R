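#' Replicate-noise model for synthetic time courses
#'
#' Emulates the scatter of independent experimental runs around the
#' deterministic model: multiplicative Gaussian noise (relative sigma, the
#' default, appropriate for signals spanning decades) or additive Gaussian
#' noise (absolute sigma). Generated values are floored (default 0: no
#' negative expression or counts).
#'
#' @param kind \code{"multiplicative_gaussian"} or
#'   \code{"additive_gaussian"}.
#' @param sigma noise scale, relative (multiplicative) or absolute
#'   (additive); >= 0.
#' @param floor minimum reportable value, >= 0.
#' @return An object of class \code{lnp_noise}.
#' @export
noise_model <- function(kind = c("multiplicative_gaussian",
                                 "additive_gaussian"),
                        sigma = 0.05, floor = 0) {
  kind <- match.arg(kind)
  if (!is.numeric(sigma) || sigma < 0 || !is.finite(sigma))
    stop("`sigma` must be finite and >= 0", call. = FALSE)
  if (!is.numeric(floor) || floor < 0)
    stop("`floor` must be >= 0", call. = FALSE)
  structure(list(kind = kind, sigma = sigma, floor = floor),
            class = "lnp_noise")
}

#' Default sampling grids for synthetic observables
#'
#' Knockdown: 10 time points over 0-21 hr, denser over the first hours the
#' way kinetic knockdown assays are sampled — the escape onset of an LNP
#' lies between 0.2 and 2 hr, so early samples are what resolve it.
#' Ago2 binding: every 0.5 hr over 0-6 hr (the span of the binding
#' assays). Cell-associated uptake: hourly over 0-12 hr.
#'
#' @param observable observable kind.
#' @return Numeric vector of times in hours.
#' @export
default_times <- function(observable = OBSERVABLES) {
  observable <- match.arg(observable)
  switch(observable,
         relative_mrna = c(0, 1, 2, 3.5, 5, 7, 9, 12, 16, 21),
         ago2_bound = seq(0, 6, by = 0.5),
         cell_associated = seq(0, 12, by = 1))
}

#' Generate a noisy synthetic time-course dataset
#'
#' Simulates the noise-free observable under the given parameters, then
#' draws \code{n_replicates} noisy copies per time point under the noise
#' model. Deterministic for a given seed; the generating parameters, the
#' clean backbone and the seed are stored as attributes.
#'
#' @param spec an [experiment_spec()] object.
#' @param params an [parameter_set()] object (the generating truth).
#' @param observable observable kind.
#' @param times sampling grid in hours (default per
#'   [default_times()]).
#' @param n_replicates replicates per time point (>= 1; default 10,
#'   matching a typical replicate structure of ten independent runs).
#' @param noise an [noise_model()] object (default 5\% multiplicative).
#' @param seed integer seed.
#' @param risc_mode free-RISC bookkeeping.
#' @param label dataset label.
#' @return An \code{lnp_timecourse} dataset with attributes
#'   \code{generating_params}, \code{clean}, \code{seed}, \code{noise}.
#' @export
generate_timecourse <- function(spec, params, observable = "relative_mrna",
                                times = default_times(observable),
                                n_replicates = 10, noise = noise_model(),
                                seed = 1,
                                risc_mode = c("conserved", "constant"),
                                label = "") {
  risc_mode <- match.arg(risc_mode)
  observable <- match.arg(observable, OBSERVABLES)
  stopifnot(inherits(noise, "lnp_noise"))
  if (n_replicates < 1) stop("`n_replicates` must be >= 1", call. = FALSE)
  grid <- sort(unique(c(0, times)))
  sim <- simulate_model(spec, params, horizon = max(grid), times = grid,
                        risc_mode = risc_mode)
  clean <- sim$observables[[observable]][match(times, sim$times)]
  set.seed(seed)
  n <- length(times) * n_replicates
  z <- stats::rnorm(n)
  base <- rep(clean, each = n_replicates)
  vals <- switch(noise$kind,
                 multiplicative_gaussian = base * (1 + noise$sigma * z),
                 additive_gaussian = base + noise$sigma * z)
  vals <- pmax(vals, noise$floor)
  ds <- timecourse_dataset(
    data.frame(time_hr = rep(times, each = n_replicates),
               value = vals,
               replicate = rep(seq_len(n_replicates), length(times))),
    observable = observable, label = label)
  attr(ds, "generating_params") <- params
  attr(ds, "clean") <- data.frame(time_hr = times, value = clean)
  attr(ds, "seed") <- seed
  attr(ds, "noise") <- noise
  ds
}

#' Reference vehicle panel
#'
#' The four delivery-vehicle profiles used throughout: the reference LNP
#' formulation (LNP201) with the full baseline constant set, and three
#' vehicles differing only in their escape kinetics — RNAiMAX (fast escape,
#' k2 = 0.004/hr, onset ~12.5 min), LNP05 (slow, k2 = 0.002/hr, onset
#' 1.75 hr) and LNP(1,3)-diether (k2 = 0.01/hr, onset 1.25 hr). Onset times
#' are midpoints of the experimentally bracketed ranges (5-20 min,
#' 1.5-2 hr, 1-1.5 hr).
#'
#' Baseline constants: k1 = 0.005/hr, k2 = 5e-4/hr, k3 = 3/hr,
#' k4 = 0.001 L/(nM hr), k5 = 0.03/hr, k6 = 0.1 L/(nM hr), k7 = 7.2/hr,
#' k8 = 100 copies/hr, k9 = 1/hr; bimolecular constants converted with the
#' intracellular volume of \code{spec}.
#'
#' @param spec an [experiment_spec()] object (volume for the k4/k6
#'   conversion).
#' @return Named list of [vehicle_profile()] objects: \code{LNP201},
#'   \code{RNAiMAX}, \code{LNP05}, \code{LNP13diether}.
#' @export
vehicle_fixtures <- function(spec = experiment_spec()) {
  base <- parameter_set_from_table(
    k1 = 0.005, k2 = 5e-4, k3 = 3, k4_L_nM_hr = 0.001, k5 = 0.03,
    k6_L_nM_hr = 0.1, k7 = 7.2, k8 = 100, k9 = 1, t_delay = 0,
    intracellular_volume = spec$intracellular_volume)
  list(
    LNP201 = vehicle_profile("LNP201", base,
                             "reference formulation, no escape delay"),
    RNAiMAX = vehicle_profile(
      "RNAiMAX",
      update_parameters(base, k2 = 0.004, t_delay = 12.5 / 60,
                        provenance = "fitted"),
      "transfection reagent; fastest escape, onset ~12.5 min"),
    LNP05 = vehicle_profile(
      "LNP05",
      update_parameters(base, k2 = 0.002, t_delay = 1.75,
                        provenance = "fitted"),
      "slow escape, onset 1.5-2 hr (midpoint 1.75 hr)"),
    LNP13diether = vehicle_profile(
      "LNP(1,3)-diether",
      update_parameters(base, k2 = 0.01, t_delay = 1.25,
                        provenance = "fitted"),
      "fast escape, onset 1-1.5 hr (midpoint 1.25 hr)"))
}
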