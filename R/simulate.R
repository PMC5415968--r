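#' Integrate the delivery model over a time horizon
#'
#' Solves the five-ODE initial-value problem with everything intracellular
#' starting at zero, mRNA at its unperturbed steady-state level
#' (\code{spec$initial_mrna}) and the extracellular pool E fixed by the
#' dose. Integration is split at the escape-onset time \code{t_delay} so the
#' Heaviside discontinuity never falls inside a solver step; within each
#' segment the effective escape rate is constant.
#'
#' Two integration routes are available: the adaptive stiff/non-stiff
#' solver (\code{method = "lsoda"}, the default) and a fixed-step classical
#' 4th-order Runge-Kutta route (\code{method = "rk4"}, step \code{step}),
#' kept as an independent cross-check of the adaptive solution. The RHS is
#' evaluated in compiled code by default; \code{engine = "r"} uses the
#' plain-R right-hand side instead.
#'
#' @param spec an [experiment_spec()] object.
#' @param params an [parameter_set()] object (canonical units).
#' @param horizon end time in hours; a warning is issued above 24 hr, the
#'   span over which the model has been validated.
#' @param times output grid in hours, strictly increasing and starting at
#'   0; default 0 to \code{horizon} at 0.1-hr resolution.
#' @param risc_mode free-RISC bookkeeping, see [free_risc()].
#' @param rtol,atol relative / absolute solver tolerances (defaults 1e-8,
#'   1e-6 molecules).
#' @param method \code{"lsoda"} (adaptive) or \code{"rk4"} (fixed step).
#' @param step fixed step size in hours for \code{method = "rk4"}.
#' @param engine \code{"compiled"} (C right-hand side) or \code{"r"}.
#' @return An object of class \code{lnp_simulation}: list with
#'   \code{times}, \code{states} (data.frame \code{time_hr}, N, S, SR, SRM,
#'   M and derived free RISC R), \code{observables} (data.frame
#'   \code{time_hr}, \code{relative_mrna}, \code{ago2_bound},
#'   \code{cell_associated}), the parameters and spec used, and solver
#'   diagnostics.
#' @examples
#' fx <- vehicle_fixtures()
#' sim <- simulate_model(experiment_spec(), fx$LNP201$parameters)
#' utils::tail(sim$observables, 1)
#' @export
simulate_model <- function(spec, params, horizon = 24, times = NULL,
                           risc_mode = c("conserved", "constant"),
                           rtol = 1e-8, atol = 1e-6,
                           method = c("lsoda", "rk4"), step = 0.001,
                           engine = c("compiled", "r")) {
  risc_mode <- match.arg(risc_mode)
  method <- match.arg(method)
  engine <- match.arg(engine)
  stopifnot(inherits(spec, "lnp_experiment"), inherits(params,
                                                       "lnp_parameters"))
  if (horizon <= 0) stop("`horizon` must be positive", call. = FALSE)
  if (horizon > 24)
    warning("horizon exceeds 24 hr; the model is validated only up to 24 hr",
            call. = FALSE)
  if (is.null(times)) times <- seq(0, horizon, by = 0.1)
  if (times[1] != 0 || is.unsorted(times, strictly = TRUE))
    stop("`times` must be strictly increasing and start at 0", call. = FALSE)
  if (max(times) > horizon)
    stop("`times` must lie within [0, horizon]", call. = FALSE)

  p <- params$values
  E <- dose_molecules_per_cell(spec)
  R0 <- spec$initial_risc
  y0 <- c(N = 0, S = 0, SR = 0, SRM = 0, M = spec$initial_mrna)
  td <- p[["t_delay"]]

  # segment boundaries: [0, t_delay] with escape off, then escape on
  breaks <- if (td > 0 && td < max(times)) c(0, td, max(times))
            else c(0, max(times))
  out <- NULL
  y <- y0
  for (i in seq_len(length(breaks) - 1L)) {
    t0 <- breaks[i]; t1 <- breaks[i + 1L]
    k2e <- if (t1 <= td) 0 else p[["k2"]]
    tseg <- sort(unique(c(t0, times[times > t0 & times <= t1], t1)))
    seg <- integrate_segment(y, tseg, p, k2e, E, R0, risc_mode,
                             rtol, atol, method, step, engine)
    y <- unlist(seg[nrow(seg), STATE_NAMES])
    keep <- seg[, "time"] %in% times
    if (!is.null(out)) keep[1] <- FALSE  # boundary row already emitted
    out <- rbind(out, seg[keep, , drop = FALSE])
  }
  bad <- out[, STATE_NAMES] < -10 * atol
  if (any(bad))
    stop("integration error: state component fell below -10*atol ",
         "(min = ", format(min(out[, STATE_NAMES])), ")", call. = FALSE)
  st <- as.data.frame(out)
  names(st)[1] <- "time_hr"
  st[STATE_NAMES] <- lapply(st[STATE_NAMES], pmax, 0)
  st$R <- free_risc(st$SR, st$SRM, R0, risc_mode)
  obs <- data.frame(
    time_hr = st$time_hr,
    relative_mrna = st$M / spec$initial_mrna,
    ago2_bound = st$SR + st$SRM,
    cell_associated = st$N + st$S + st$SR + st$SRM)
  structure(
    list(times = st$time_hr, states = st, observables = obs,
         params_used = params, spec = spec, risc_mode = risc_mode,
         solver_diagnostics = list(method = method, engine = engine,
                                   rtol = rtol, atol = atol, step = step,
                                   segments = breaks)),
    class = "lnp_simulation")
}

# One smooth segment: constant effective escape rate k2e.
integrate_segment <- function(y, tseg, p, k2e, E, R0, risc_mode,
                              rtol, atol, method, step, engine) {
  if (length(tseg) == 1L)
    return(matrix(c(tseg, y), nrow = 1,
                  dimnames = list(NULL, c("time", STATE_NAMES))))
  parms <- c(p[["k1"]], k2e, p[["k3"]], p[["k4"]], p[["k5"]], p[["k6"]],
             p[["k7"]], p[["k8"]], p[["k9"]], E, R0,
             as.numeric(risc_mode == "conserved"))
  if (method == "rk4") {
    # fixed-step grid, refined to `step`, with the requested output times
    # merged in (a short partial step can occur before each output time)
    grid <- sort(unique(c(seq(tseg[1], tseg[length(tseg)], by = step), tseg)))
    sol <- run_ode(y, grid, parms, engine, "rk4", rtol, atol)
    sol <- sol[grid %in% tseg, , drop = FALSE]
  } else {
    sol <- deSolve_checked(run_ode(y, tseg, parms, engine, "lsoda",
                                   rtol, atol))
  }
  colnames(sol) <- c("time", STATE_NAMES)
  sol
}

run_ode <- function(y, times, parms, engine, method, rtol = 1e-8,
                    atol = 1e-6) {
  if (engine == "compiled") {
    deSolve::ode(y = y, times = times, func = "lnp_derivs", parms = parms,
                 dllname = "lnpkinetics", initfunc = "lnp_initmod",
                 method = method, rtol = rtol, atol = atol)
  } else {
    rhs <- function(t, y, pm) {
      R <- if (pm[12] > 0) max(pm[11] - y[3] - y[4], 0) else pm[11]
      list(c(pm[1] * pm[10] - (pm[2] + pm[3]) * y[1],
             pm[2] * y[1] - pm[5] * y[2] - pm[4] * y[2] * R,
             pm[4] * y[2] * R - pm[6] * y[5] * y[3],
             pm[6] * y[5] * y[3] - pm[7] * y[4],
             pm[8] - pm[9] * y[5] - pm[7] * y[4]))
    }
    deSolve::ode(y = y, times = times, func = rhs, parms = parms,
                 method = method, rtol = rtol, atol = atol)
  }
}

deSolve_checked <- function(sol) {
  istate <- attr(sol, "istate")
  if (!is.null(istate) && istate[1] < 0)
    stop("integration error: solver reported istate = ", istate[1],
         call. = FALSE)
  sol
}

#' @export
print.lnp_simulation <- function(x, ...) {
  cat("<lnp_simulation>\n")
  cat(sprintf("  %d time points over [0, %g] hr (%s, %s engine, %s RISC)\n",
              length(x$times), max(x$times), x$solver_diagnostics$method,
              x$solver_diagnostics$engine, x$risc_mode))
  n <- length(x$times)
  cat(sprintf("  relative mRNA at %g hr: %.4f\n", x$times[n],
              x$observables$relative_mrna[n]))
  invisible(x)
}

#' Relative mRNA knockdown time course
#'
#' Target mRNA normalized to its initial (steady-state) level,
#' M(t) / M(0); 1 means no silencing.
#'
#' @param result an [simulate_model()] result.
#' @return data.frame with columns \code{time_hr}, \code{value} (fraction).
#' @export
knockdown_timecourse <- function(result) {
  stopifnot(inherits(result, "lnp_simulation"))
  M0 <- result$states$M[1]
  if (M0 == 0)
    stop("undefined normalization: M(0) = 0", call. = FALSE)
  data.frame(time_hr = result$times, value = result$states$M / M0)
}

#' Ago2-bound siRNA time course
#'
#' The immunoprecipitation-style readout: by default the sum of the
#' Ago2-bound pool and the active complex (SR + SRM), since pulling down
#' Ago2 captures both; set \code{include_srm = FALSE} for SR alone.
#'
#' @param result an [simulate_model()] result.
#' @param include_srm include the active RISC-mRNA complex (default TRUE).
#' @return data.frame with columns \code{time_hr}, \code{value}
#'   (molecules/cell).
#' @export
ago2_binding_timecourse <- function(result, include_srm = TRUE) {
  stopifnot(inherits(result, "lnp_simulation"))
  v <- if (include_srm) result$states$SR + result$states$SRM
       else result$states$SR
  data.frame(time_hr = result$times, value = v)
}

#' Cell-associated siRNA time course
#'
#' Proxy for a fluorescent-label uptake signal: the label travels with the
#' siRNA, so the total N + S + SR + SRM is reported.
#'
#' @param result an [simulate_model()] result.
#' @return data.frame with columns \code{time_hr}, \code{value}
#'   (molecules/cell).
#' @export
uptake_timecourse <- function(result) {
  stopifnot(inherits(result, "lnp_simulation"))
  data.frame(time_hr = result$times,
             value = with(result$states, N + S + SR + SRM))
}

#' Time to a given fraction of the plateau effect
#'
#' Earliest time at which a series crosses
#' \code{value(0) + level * (plateau - value(0))}, where the plateau is the
#' final value of the series; found by linear interpolation between
#' samples. For a series starting at 0 this is the time to reach
#' \code{level} times the plateau. Works for rising (Ago2 binding, uptake)
#' and falling (knockdown) series alike.
#'
#' @param series data.frame with columns \code{time_hr} and \code{value}.
#' @param level fraction of the initial-to-plateau excursion, in (0, 1).
#' @return Crossing time in hours, or \code{NA_real_} if the threshold is
#'   never reached (e.g. a constant series).
#' @export
time_to_half_effect <- function(series, level = 0.5) {
  if (!is.data.frame(series) || !all(c("time_hr", "value") %in% names(series)))
    stop("`series` must be a data.frame with columns time_hr and value",
         call. = FALSE)
  if (nrow(series) == 0) stop("`series` is empty", call. = FALSE)
  if (level <= 0 || level >= 1)
    stop("`level` must be in (0, 1)", call. = FALSE)
  t <- series$time_hr; v <- series$value
  v0 <- v[1]; plateau <- v[length(v)]
  if (plateau == v0) return(NA_real_)
  thr <- v0 + level * (plateau - v0)
  rising <- plateau > v0
  hit <- if (rising) v >= thr else v <= thr
  i <- which(hit)[1]
  if (is.na(i)) return(NA_real_)
  if (i == 1L) return(t[1])
  # linear interpolation on the bracketing interval
  t[i - 1] + (thr - v[i - 1]) / (v[i] - v[i - 1]) * (t[i] - t[i - 1])
}

#' Write a simulation to CSV with a reproducibility manifest
#'
#' Writes columns \code{time_hr, N, S, SR, SRM, M, R, relative_mrna,
#' ago2_bound, cell_associated} and a JSON sidecar
#' (\code{<path>.manifest.json}) recording the parameters, experiment,
#' solver settings and package version.
#'
#' @param result an [simulate_model()] result.
#' @param path output CSV path.
#' @param command optional command string recorded in the manifest.
#' @param seed optional seed recorded in the manifest.
#' @return \code{path}, invisibly.
#' @export
write_simulation_csv <- function(result, path, command = NULL, seed = NULL) {
  stopifnot(inherits(result, "lnp_simulation"))
  df <- cbind(result$states,
              result$observables[, c("relative_mrna", "ago2_bound",
                                     "cell_associated")])
  utils::write.csv(df, path, row.names = FALSE)
  write_manifest(path, command = command %||% "simulate",
                 arguments = list(),
                 config = list(parameters = as.list(result$params_used$values),
                               experiment = unclass(result$spec),
                               risc_mode = result$risc_mode,
                               solver = result$solver_diagnostics),
                 seed = seed)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
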