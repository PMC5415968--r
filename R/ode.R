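STATE_NAMES <- c("N", "S", "SR", "SRM", "M")

#' Heaviside-delayed endosomal escape rate
#'
#' Escape from the endosome is modeled as switched on at \code{t_delay}:
#' the effective rate is 0 for \code{t < t_delay} and \code{k2} for
#' \code{t >= t_delay} (onset inclusive, H(0) = 1).
#'
#' @param t time in hours (vectorized), >= 0.
#' @param params an [parameter_set()] object.
#' @return Effective escape rate(s) in 1/hr.
#' @export
effective_escape_rate <- function(t, params) {
  stopifnot(inherits(params, "lnp_parameters"))
  if (any(t < 0)) stop("`t` must be >= 0", call. = FALSE)
  ifelse(t >= params$values[["t_delay"]], params$values[["k2"]], 0)
}

#' Free RISC given the bound pools
#'
#' In the default \code{"conserved"} bookkeeping the RISC pool is finite:
#' R = max(R0 - SR - SRM, 0). In \code{"constant"} mode R is pinned at R0,
#' reproducing the printed equations literally.
#'
#' @param SR,SRM Ago2-bound siRNA and active-complex pools, molecules/cell.
#' @param initial_risc R0, molecules/cell.
#' @param risc_mode \code{"conserved"} or \code{"constant"}.
#' @return Free RISC, molecules/cell.
#' @export
free_risc <- function(SR, SRM, initial_risc,
                      risc_mode = c("conserved", "constant")) {
  risc_mode <- match.arg(risc_mode)
  if (risc_mode == "constant") rep(initial_risc, length(SR))
  else pmax(initial_risc - SR - SRM, 0)
}

#' Right-hand side of the delivery model
#'
#' The five coupled ODEs for endosomal LNP-siRNA (N), free cytoplasmic
#' siRNA (S), Ago2-bound siRNA (SR), active RISC-mRNA complex (SRM) and
#' target mRNA (M), with constant extracellular siRNA E and free RISC R
#' derived per \code{risc_mode}:
#' \deqn{dN/dt = k_1 E - (k_{2,eff}(t) + k_3) N}
#' \deqn{dS/dt = k_{2,eff}(t) N - k_5 S - k_4 S R}
#' \deqn{dSR/dt = k_4 S R - k_6 M\,SR}
#' \deqn{dSRM/dt = k_6 M\,SR - k_7 SRM}
#' \deqn{dM/dt = k_8 - k_9 M - k_7 SRM}
#' with \eqn{k_{2,eff}} from [effective_escape_rate()].
#'
#' @param t time, hours.
#' @param state named numeric vector with components N, S, SR, SRM, M
#'   (molecules/cell), all finite and >= 0.
#' @param params an [parameter_set()] object.
#' @param spec an [experiment_spec()] object (supplies E and R0).
#' @param risc_mode free-RISC bookkeeping, see [free_risc()].
#' @return Named numeric vector of the five derivatives
#'   (molecules/cell/hr).
#' @export
ode_derivatives <- function(t, state, params, spec,
                            risc_mode = c("conserved", "constant")) {
  risc_mode <- match.arg(risc_mode)
  stopifnot(inherits(params, "lnp_parameters"),
            inherits(spec, "lnp_experiment"))
  state <- state[STATE_NAMES]
  if (any(!is.finite(state)))
    stop("state components must be finite", call. = FALSE)
  if (any(state < 0))
    stop("state components must be >= 0", call. = FALSE)
  p <- params$values
  E <- dose_molecules_per_cell(spec)
  k2e <- effective_escape_rate(t, params)
  R <- free_risc(state[["SR"]], state[["SRM"]], spec$initial_risc, risc_mode)
  with(as.list(state), c(
    N = p[["k1"]] * E - (k2e + p[["k3"]]) * N,
    S = k2e * N - p[["k5"]] * S - p[["k4"]] * S * R,
    SR = p[["k4"]] * S * R - p[["k6"]] * M * SR,
    SRM = p[["k6"]] * M * SR - p[["k7"]] * SRM,
    M = p[["k8"]] - p[["k9"]] * M - p[["k7"]] * SRM))
}

#' Unperturbed steady-state mRNA level
#'
#' With no active silencing complex, \eqn{dM/dt = k_8 - k_9 M} has the
#' fixed point \eqn{M^* = k_8 / k_9}; the model's initial mRNA level is set
#' at this steady state.
#'
#' @param params an [parameter_set()] object with \code{k9 > 0}.
#' @return Steady-state mRNA, molecules/cell.
#' @export
steady_state_mrna <- function(params) {
  stopifnot(inherits(params, "lnp_parameters"))
  k9 <- params$values[["k9"]]
  if (k9 <= 0)
    stop("no steady state: k9 must be > 0", call. = FALSE)
  params$values[["k8"]] / k9
}

# Jacobian of the RHS w.r.t. the state, at fixed effective escape rate.
# In conserved mode (and R > 0) dR/dSR = dR/dSRM = -1; at the R = 0 floor
# those derivatives vanish.
state_jacobian <- function(state, p, E, R0, k2e, risc_mode) {
  N <- state[[1]]; S <- state[[2]]; SR <- state[[3]]
  SRM <- state[[4]]; M <- state[[5]]
  conserved <- risc_mode == "conserved"
  R <- if (conserved) max(R0 - SR - SRM, 0) else R0
  dR <- if (conserved && (R0 - SR - SRM) > 0) -1 else 0
  J <- matrix(0, 5, 5, dimnames = list(STATE_NAMES, STATE_NAMES))
  J["N", "N"] <- -(k2e + p[["k3"]])
  J["S", "N"] <- k2e
  J["S", "S"] <- -p[["k5"]] - p[["k4"]] * R
  J["S", "SR"] <- -p[["k4"]] * S * dR
  J["S", "SRM"] <- -p[["k4"]] * S * dR
  J["SR", "S"] <- p[["k4"]] * R
  J["SR", "SR"] <- p[["k4"]] * S * dR - p[["k6"]] * M
  J["SR", "SRM"] <- p[["k4"]] * S * dR
  J["SR", "M"] <- -p[["k6"]] * SR
  J["SRM", "SR"] <- p[["k6"]] * M
  J["SRM", "SRM"] <- -p[["k7"]]
  J["SRM", "M"] <- p[["k6"]] * SR
  J["M", "SRM"] <- -p[["k7"]]
  J["M", "M"] <- -p[["k9"]]
  J
}

# Partial derivative of the RHS w.r.t. one rate constant, at fixed state.
# k2 enters only after onset (escape_on); t_delay has no smooth derivative
# and is handled by finite differences elsewhere.
param_partial <- function(target, state, p, E, R0, escape_on, risc_mode) {
  N <- state[[1]]; S <- state[[2]]; SR <- state[[3]]
  SRM <- state[[4]]; M <- state[[5]]
  R <- if (risc_mode == "conserved") max(R0 - SR - SRM, 0) else R0
  switch(target,
    k1 = c(E, 0, 0, 0, 0),
    k2 = if (escape_on) c(-N, N, 0, 0, 0) else numeric(5),
    k3 = c(-N, 0, 0, 0, 0),
    k4 = c(0, -S * R, S * R, 0, 0),
    k5 = c(0, -S, 0, 0, 0),
    k6 = c(0, 0, -M * SR, M * SR, 0),
    k7 = c(0, 0, 0, -SRM, -SRM),
    k8 = c(0, 0, 0, 0, 1),
    k9 = c(0, 0, 0, 0, -M),
    stop("unknown sensitivity target: ", target, call. = FALSE))
}
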