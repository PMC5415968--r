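#' Forward (auxiliary-ODE) local sensitivities of mRNA to the rate constants
#'
#' Augments the five state equations with the forward sensitivity system
#' \eqn{ds_j/dt = J(y, t)\, s_j + \partial f / \partial k_j}, \eqn{s_j(0) =
#' 0}, where J is the state Jacobian, and integrates states and
#' sensitivities together. Only the mRNA rows \eqn{\partial M / \partial
#' k_j} are reported, both raw and in normalized (logarithmic) form
#' \eqn{(k_j / M) \partial M / \partial k_j}, which is unit-free and
#' comparable across parameters. The Heaviside escape onset is handled by
#' segment-splitting exactly as in [simulate_model()].
#'
#' The onset time \code{t_delay} has no smooth derivative (the escape term
#' is a step in time); use [finite_difference_sensitivities()] for it.
#'
#' @param spec an [experiment_spec()] object.
#' @param params an [parameter_set()] object.
#' @param horizon end time, hours.
#' @param times output grid (default 0.1-hr resolution).
#' @param targets subset of \code{k1}..\code{k9}.
#' @param risc_mode free-RISC bookkeeping, see [free_risc()].
#' @param rtol,atol solver tolerances.
#' @return An object of class \code{lnp_sensitivity}: \code{times}, and
#'   \code{raw} / \code{normalized} matrices (times x targets) of
#'   \eqn{\partial M/\partial k_j}.
#' @export
forward_sensitivities <- function(spec, params, horizon = 24, times = NULL,
                                  targets = RATE_NAMES,
                                  risc_mode = c("conserved", "constant"),
                                  rtol = 1e-8, atol = 1e-6) {
  risc_mode <- match.arg(risc_mode)
  stopifnot(inherits(spec, "lnp_experiment"), inherits(params,
                                                       "lnp_parameters"))
  if (horizon <= 0) stop("`horizon` must be positive", call. = FALSE)
  if (!all(targets %in% RATE_NAMES))
    stop("`targets` must be a subset of k1..k9", call. = FALSE)
  if (is.null(times)) times <- seq(0, horizon, by = 0.1)
  if (times[1] != 0 || is.unsorted(times, strictly = TRUE))
    stop("`times` must be strictly increasing and start at 0", call. = FALSE)

  p <- params$values
  E <- dose_molecules_per_cell(spec)
  R0 <- spec$initial_risc
  np <- length(targets)
  y0 <- c(c(N = 0, S = 0, SR = 0, SRM = 0, M = spec$initial_mrna),
          rep(0, 5L * np))
  td <- p[["t_delay"]]
  breaks <- if (td > 0 && td < max(times)) c(0, td, max(times))
            else c(0, max(times))

  aug_rhs <- function(t, y, env) {
    state <- y[1:5]
    if (any(state < 0)) state <- pmax(state, 0)
    J <- state_jacobian(state, p, E, R0, env$k2e, risc_mode)
    Smat <- matrix(y[-(1:5)], nrow = 5L, ncol = np)
    Fp <- vapply(targets, function(tg)
      param_partial(tg, state, p, E, R0, env$escape_on, risc_mode),
      numeric(5))
    ds <- fv <- numeric(5)
    N <- state[[1]]; S <- state[[2]]; SR <- state[[3]]
    SRM <- state[[4]]; M <- state[[5]]
    R <- if (risc_mode == "conserved") max(R0 - SR - SRM, 0) else R0
    fv[1] <- p[["k1"]] * E - (env$k2e + p[["k3"]]) * N
    fv[2] <- env$k2e * N - p[["k5"]] * S - p[["k4"]] * S * R
    fv[3] <- p[["k4"]] * S * R - p[["k6"]] * M * SR
    fv[4] <- p[["k6"]] * M * SR - p[["k7"]] * SRM
    fv[5] <- p[["k8"]] - p[["k9"]] * M - p[["k7"]] * SRM
    dS <- J %*% Smat + Fp
    list(c(fv, as.vector(dS)))
  }

  out <- NULL
  y <- y0
  for (i in seq_len(length(breaks) - 1L)) {
    t0 <- breaks[i]; t1 <- breaks[i + 1L]
    env <- list(k2e = if (t1 <= td) 0 else p[["k2"]],
                escape_on = t1 > td)
    tseg <- sort(unique(c(t0, times[times > t0 & times <= t1], t1)))
    if (length(tseg) > 1L) {
      sol <- deSolve::ode(y = y, times = tseg, func = aug_rhs, parms = env,
                          method = "lsoda", rtol = rtol, atol = atol)
      y <- sol[nrow(sol), -1]
      keep <- sol[, 1] %in% times
      if (!is.null(out)) keep[1] <- FALSE
      out <- rbind(out, sol[keep, , drop = FALSE])
    }
  }
  tt <- out[, 1]
  M <- out[, 6]
  # dM/dk_j is row 5 of each sensitivity block
  raw <- vapply(seq_len(np), function(j) out[, 1 + 5L * j + 5L], numeric(
    length(tt)))
  raw <- matrix(raw, ncol = np, dimnames = list(NULL, targets))
  normalized <- sweep(raw, 2, p[targets], `*`) / ifelse(M > 0, M, NA_real_)
  structure(
    list(times = tt, raw = raw, normalized = normalized, targets = targets,
         params = params, spec = spec, risc_mode = risc_mode),
    class = "lnp_sensitivity")
}

#' @export
print.lnp_sensitivity <- function(x, ...) {
  cat("<lnp_sensitivity>\n")
  cat(sprintf("  %d time points, targets: %s\n", length(x$times),
              paste(x$targets, collapse = ", ")))
  invisible(x)
}

#' Central finite-difference sensitivities of mRNA
#'
#' Independent route to \eqn{\partial M/\partial \theta} by central
#' differences, \code{(M(theta(1+h)) - M(theta(1-h))) / (2 theta h)}. Also
#' the only route for \code{t_delay}, whose Heaviside onset admits no
#' forward sensitivity equation (for \code{t_delay = 0} a one-sided forward
#' difference is used).
#'
#' @inheritParams forward_sensitivities
#' @param targets subset of \code{k1}..\code{k9}, \code{t_delay}.
#' @param rel_step relative perturbation step (default 1e-4).
#' @param rtol,atol solver tolerances for the perturbed runs; tighter than
#'   the simulation defaults because the differenced signal can sit only a
#'   few orders of magnitude above the integration error.
#' @return List with \code{times} and \code{raw} (times x targets matrix).
#' @export
finite_difference_sensitivities <- function(spec, params, horizon = 24,
                                            times = NULL,
                                            targets = RATE_NAMES,
                                            risc_mode = c("conserved",
                                                          "constant"),
                                            rel_step = 1e-4,
                                            rtol = 1e-10, atol = 1e-9) {
  risc_mode <- match.arg(risc_mode)
  if (is.null(times)) times <- seq(0, horizon, by = 0.1)
  if (!all(targets %in% PARAM_NAMES))
    stop("`targets` must be among k1..k9, t_delay", call. = FALSE)
  mrna_at <- function(pp) {
    simulate_model(spec, pp, horizon = horizon, times = times,
                   risc_mode = risc_mode, rtol = rtol, atol = atol)$states$M
  }
  raw <- vapply(targets, function(tg) {
    th <- params$values[[tg]]
    if (th > 0) {
      h <- th * rel_step
      up <- do.call(update_parameters,
                    stats::setNames(list(params, th + h), c("params", tg)))
      dn <- do.call(update_parameters,
                    stats::setNames(list(params, th - h), c("params", tg)))
      (mrna_at(up) - mrna_at(dn)) / (2 * h)
    } else {
      h <- rel_step
      up <- do.call(update_parameters,
                    stats::setNames(list(params, h), c("params", tg)))
      (mrna_at(up) - mrna_at(params)) / h
    }
  }, numeric(length(times)))
  list(times = times,
       raw = matrix(raw, ncol = length(targets),
                    dimnames = list(NULL, targets)))
}

#' Rank parameters by integrated absolute sensitivity
#'
#' The default importance score of parameter \eqn{k_j} is the time
#' integral (trapezoidal) of the absolute raw time-dependent derivative
#' \eqn{|\partial M/\partial k_j|} over the horizon, with the bimolecular
#' constants expressed in their tabulated L/(nM hr) units so every
#' derivative is taken with respect to the constant as tabulated. Under
#' this metric the escape constant k2 — by far the smallest first-order
#' constant with leverage on silencing — dominates, with k1 and k4 next.
#'
#' \code{metric = "normalized"} instead integrates the unit-free
#' logarithmic sensitivities \eqn{|(k_j/M)\,\partial M/\partial k_j|}; note
#' that under it the transcription/turnover pair k8, k9 trivially scores
#' near 1 per unit time (mRNA is proportional to k8/k9 regardless of
#' silencing), which says nothing about delivery.
#'
#' @param result an [forward_sensitivities()] result.
#' @param metric \code{"raw_table_units"} (default) or
#'   \code{"normalized"}.
#' @return data.frame with columns \code{parameter}, \code{score}, sorted
#'   descending by score (ties broken by parameter name).
#' @export
rank_parameters <- function(result,
                            metric = c("raw_table_units", "normalized")) {
  stopifnot(inherits(result, "lnp_sensitivity"))
  metric <- match.arg(metric)
  tt <- result$times
  mat <- if (metric == "normalized") result$normalized else {
    m <- result$raw
    # d(M)/d(k in L/nM*hr) = d(M)/d(k per-cell) * per-cell-per-nM factor
    conv <- 1e-9 * result$spec$intracellular_volume * AVOGADRO
    for (bi in intersect(c("k4", "k6"), colnames(m)))
      m[, bi] <- m[, bi] / conv
    m
  }
  score <- apply(abs(mat), 2, function(v) {
    v[is.na(v)] <- 0
    trapezoid(tt, v)
  })
  out <- data.frame(parameter = result$targets, score = as.numeric(score))
  out[order(-out$score, out$parameter), , drop = FALSE]
}

trapezoid <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)]) / 2)

#' One-at-a-time logarithmic parameter scan
#'
#' Re-simulates the model once per grid value with a single parameter
#' replaced, and reports the endpoint relative mRNA per value (plus the
#' full knockdown curve). A simulation failure at one grid point is
#' recorded as \code{NA} without aborting the scan.
#'
#' @inheritParams forward_sensitivities
#' @param target one of \code{k1}..\code{k9}, \code{t_delay}.
#' @param values grid of parameter values (canonical units), all > 0 for
#'   rate constants; typically log-spaced, see [scan_grid()] and
#'   [scan_presets()].
#' @return An object of class \code{lnp_scan}: \code{table} (data.frame
#'   \code{value}, \code{relative_mrna_end}), \code{curves} (list of
#'   knockdown data.frames), \code{target}, \code{horizon}.
#' @export
parameter_scan <- function(spec, params, target, values, horizon = 24,
                           times = NULL,
                           risc_mode = c("conserved", "constant")) {
  risc_mode <- match.arg(risc_mode)
  if (length(target) != 1L || !target %in% PARAM_NAMES)
    stop("`target` must be one of k1..k9, t_delay", call. = FALSE)
  if (target != "t_delay" && any(values <= 0))
    stop("scan grid values must be > 0", call. = FALSE)
  if (is.null(times)) times <- seq(0, horizon, by = 0.1)
  curves <- vector("list", length(values))
  end <- rep(NA_real_, length(values))
  for (i in seq_along(values)) {
    pp <- do.call(update_parameters,
                  stats::setNames(list(params, values[i]),
                                  c("params", target)))
    sim <- tryCatch(
      simulate_model(spec, pp, horizon = horizon, times = times,
                     risc_mode = risc_mode),
      error = function(e) {
        warning(sprintf("scan point %s = %g failed: %s", target, values[i],
                        conditionMessage(e)), call. = FALSE)
        NULL
      })
    if (!is.null(sim)) {
      kd <- knockdown_timecourse(sim)
      curves[[i]] <- kd
      end[i] <- kd$value[nrow(kd)]
    }
  }
  structure(list(table = data.frame(value = values,
                                    relative_mrna_end = end),
                 curves = curves, target = target, horizon = horizon,
                 params = params, spec = spec),
            class = "lnp_scan")
}

#' @export
print.lnp_scan <- function(x, ...) {
  cat(sprintf("<lnp_scan> %s over [%g, %g], %d points\n", x$target,
              min(x$table$value), max(x$table$value), nrow(x$table)))
  cat(sprintf("  min endpoint relative mRNA: %.4g at %s = %.4g\n",
              min(x$table$relative_mrna_end, na.rm = TRUE), x$target,
              x$table$value[which.min(x$table$relative_mrna_end)]))
  invisible(x)
}

#' Log-spaced scan grid
#'
#' @param from,to positive range endpoints.
#' @param n number of points (default 25).
#' @return Numeric vector of \code{n} log-spaced values.
#' @export
scan_grid <- function(from, to, n = 25) {
  if (from <= 0 || to <= from) stop("need 0 < from < to", call. = FALSE)
  10^seq(log10(from), log10(to), length.out = n)
}

#' Named scan presets for the uptake, escape and loading constants
#'
#' Grids spanning the ranges explored for the three key constants: uptake
#' \code{k1} from its reference value up 1000-fold, escape \code{k2} from
#' 1e-4 to 500 (about six orders of magnitude), and RISC loading \code{k4}
#' from 0.001 to 10 L/(nM hr) (converted to canonical per-cell units using
#' the spec's intracellular volume).
#'
#' @param spec an [experiment_spec()] object (supplies the volume for the
#'   \code{k4} conversion).
#' @param n points per grid (default 25).
#' @return Named list of numeric grids (canonical units) for \code{k1},
#'   \code{k2}, \code{k4}.
#' @export
scan_presets <- function(spec = experiment_spec(), n = 25) {
  list(
    k1 = scan_grid(0.005, 5, n),
    k2 = scan_grid(1e-4, 500, n),
    k4 = scan_grid(
      bimolecular_rate_to_percell(0.001, spec$intracellular_volume),
      bimolecular_rate_to_percell(10, spec$intracellular_volume), n))
}
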