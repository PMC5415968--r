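OBSERVABLES <- c("relative_mrna", "ago2_bound", "cell_associated")

#' Construct a time-course dataset
#'
#' Wraps observed (or synthetic) records of one observable into the
#' structure used for fitting: a data.frame with columns \code{time_hr},
#' \code{value}, \code{replicate}, plus per-record weights and a label.
#'
#' @param data data.frame with columns \code{time_hr} and \code{value};
#'   an optional \code{replicate} column (missing = one replicate).
#' @param observable one of \code{"relative_mrna"}, \code{"ago2_bound"},
#'   \code{"cell_associated"}.
#' @param label vehicle/cargo label.
#' @param weights per-record positive weights, recycled (default 1,
#'   i.e. unweighted least squares on the observable scale).
#' @return An object of class \code{lnp_timecourse}.
#' @export
timecourse_dataset <- function(data, observable, label = "",
                               weights = 1) {
  observable <- match.arg(observable, OBSERVABLES)
  if (!is.data.frame(data) || !all(c("time_hr", "value") %in% names(data)))
    stop("`data` must have columns time_hr and value", call. = FALSE)
  if (is.null(data$replicate)) data$replicate <- 1L
  if (any(!is.finite(data$time_hr)) || any(data$time_hr < 0) ||
      any(data$time_hr > 24))
    stop("times must be finite and within [0, 24] hr", call. = FALSE)
  if (any(!is.finite(data$value)))
    stop("values must be finite", call. = FALSE)
  if (observable == "relative_mrna" &&
      (any(data$value < 0) || any(data$value > 1.3)))
    warning("relative_mrna values outside [0, 1.3] look un-normalized",
            call. = FALSE)
  w <- rep_len(weights, nrow(data))
  if (any(!is.finite(w)) || any(w <= 0))
    stop("weights must be positive and finite", call. = FALSE)
  structure(data[c("time_hr", "value", "replicate")],
            observable = observable, label = label, weights = w,
            class = c("lnp_timecourse", "data.frame"))
}

#' Read a time-course CSV
#'
#' Expects columns \code{time_hr}, \code{value} and optionally
#' \code{replicate} and \code{observable} (a single observable per file;
#' without the column, \code{observable} must be supplied).
#'
#' @param path CSV path.
#' @param observable observable kind if the file has no such column.
#' @param label dataset label.
#' @return An \code{lnp_timecourse} object.
#' @export
read_timecourse_csv <- function(path, observable = NULL, label = basename(
  path)) {
  df <- utils::read.csv(path)
  if ("observable" %in% names(df)) {
    obs <- unique(df$observable)
    if (length(obs) != 1L)
      stop("file mixes observables; one observable per dataset",
           call. = FALSE)
    observable <- obs
  }
  if (is.null(observable))
    stop("no `observable` column in file and none supplied", call. = FALSE)
  timecourse_dataset(df, observable = observable, label = label)
}

#' Write a time-course dataset to CSV
#' @param dataset an \code{lnp_timecourse} object.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_timecourse_csv <- function(dataset, path) {
  stopifnot(inherits(dataset, "lnp_timecourse"))
  df <- as.data.frame(dataset)
  df$observable <- attr(dataset, "observable")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

FREE_PARAMS <- c("k1", "k2", "k4", "t_delay")

#' Weighted residuals of the model against time-course datasets
#'
#' Substitutes the free-parameter values into the base parameter set, runs
#' one simulation per dataset (evaluated exactly at the data times), and
#' returns the concatenated weighted residuals \code{w * (observed -
#' predicted)} on the observable scale.
#'
#' @param datasets a single \code{lnp_timecourse} or a list of them.
#' @param spec an [experiment_spec()] object.
#' @param base_params an [parameter_set()] object supplying the fixed
#'   parameters.
#' @param free character vector among \code{k1, k2, k4, t_delay}.
#' @param values numeric vector of trial values for \code{free} (canonical
#'   units, linear scale).
#' @param risc_mode free-RISC bookkeeping.
#' @param on_error \code{"penalty"} (default) replaces residuals of a
#'   failed simulation with a large constant so optimizers survive;
#'   \code{"error"} rethrows.
#' @return Numeric residual vector, one element per record.
#' @export
fit_residuals <- function(datasets, spec, base_params, free, values,
                          risc_mode = c("conserved", "constant"),
                          on_error = c("penalty", "error")) {
  risc_mode <- match.arg(risc_mode)
  on_error <- match.arg(on_error)
  datasets <- as_dataset_list(datasets)
  if (!all(free %in% FREE_PARAMS))
    stop("`free` must be among ", paste(FREE_PARAMS, collapse = ", "),
         call. = FALSE)
  if (length(values) != length(free))
    stop("`values` must match `free` in length", call. = FALSE)
  pp <- do.call(update_parameters,
                c(list(params = base_params), as.list(stats::setNames(
                  values, free))))
  unlist(lapply(datasets, function(ds) {
    dt <- ds$time_hr
    grid <- sort(unique(c(0, dt)))
    sim <- tryCatch(
      simulate_model(spec, pp, horizon = max(grid), times = grid,
                     risc_mode = risc_mode),
      error = function(e) {
        if (on_error == "error") stop(e)
        warning("simulation failed during fitting (penalized): ",
                conditionMessage(e), call. = FALSE)
        NULL
      })
    if (is.null(sim)) return(rep(1e6, nrow(ds)))
    pred <- sim$observables[[attr(ds, "observable")]]
    pred <- pred[match(dt, sim$times)]
    attr(ds, "weights") * (ds$value - pred)
  }), use.names = FALSE)
}

as_dataset_list <- function(datasets) {
  if (inherits(datasets, "lnp_timecourse")) datasets <- list(datasets)
  if (!length(datasets) || !all(vapply(datasets, inherits, logical(1),
                                       "lnp_timecourse")))
    stop("`datasets` must be lnp_timecourse objects", call. = FALSE)
  datasets
}

default_bounds <- function(base_params, free) {
  v <- base_params$values
  lapply(stats::setNames(free, free), function(nm) {
    if (nm == "t_delay") return(c(0, 6))
    b <- v[[nm]]
    if (b <= 0)
      stop("cannot derive default bounds for ", nm,
           " from a zero baseline; supply `bounds`", call. = FALSE)
    c(b / 1000, b * 1000)
  })
}

#' Fit free parameters to time-course data by bounded least squares
#'
#' Minimizes the (weighted) sum of squared residuals over the chosen free
#' parameters, with rate constants optimized on a log10 scale (they span
#' many orders of magnitude) and \code{t_delay} on a linear scale. The
#' optimizer (\code{\link[stats]{nlminb}}) is started from \code{n_starts}
#' Latin-hypercube points spread over the (transformed) bounding box; the
#' best converged start wins. Deterministic for a given seed.
#'
#' When two or more parameters are fitted, an approximate correlation
#' matrix from the residual Jacobian at the optimum is inspected and a
#' warning is raised if any pair is correlated above 0.99 in magnitude
#' (a practical non-identifiability flag, common when fitting several
#' constants to knockdown data alone).
#'
#' @inheritParams fit_residuals
#' @param free parameters to estimate, among \code{k1, k2, k4, t_delay}.
#' @param bounds named list of \code{c(lower, upper)} per free parameter
#'   (canonical units); default: rate constants within 1000-fold of the
#'   base value either way, \code{t_delay} in [0, 6] hr.
#' @param n_starts number of multi-start points (>= 1, default 16).
#' @param seed integer seed for the Latin-hypercube draw.
#' @return An object of class \code{lnp_fit}: \code{estimates} (named
#'   vector, canonical units), \code{objective} (SSR at the estimate),
#'   \code{n_obs}, \code{starts} (per-start diagnostics data.frame),
#'   \code{bounds}, \code{bounds_hit}, \code{seed}, and the inputs needed
#'   to reproduce the residuals.
#' @export
fit_vehicle <- function(datasets, spec, base_params,
                        free = c("k1", "k2", "k4"), bounds = NULL,
                        n_starts = 16, seed = 1,
                        risc_mode = c("conserved", "constant")) {
  risc_mode <- match.arg(risc_mode)
  datasets <- as_dataset_list(datasets)
  free <- match.arg(free, FREE_PARAMS, several.ok = TRUE)
  if (n_starts < 1) stop("`n_starts` must be >= 1", call. = FALSE)
  for (ds in datasets)
    if (length(unique(ds$time_hr)) < 4)
      stop("each dataset needs at least 4 distinct time points",
           call. = FALSE)
  if (is.null(bounds)) bounds <- default_bounds(base_params, free)
  if (!all(free %in% names(bounds)))
    stop("`bounds` must cover every free parameter", call. = FALSE)
  bl <- vapply(bounds[free], `[`, numeric(1), 1L)
  bu <- vapply(bounds[free], `[`, numeric(1), 2L)
  if (any(!is.finite(bl)) || any(!is.finite(bu)) || any(bl >= bu) ||
      any(bl < 0) || any(bl == 0 & free != "t_delay"))
    stop("bounds must be finite, positive for rates, lower < upper",
         call. = FALSE)

  is_rate <- free != "t_delay"
  to_opt <- function(x) ifelse(is_rate, log10(x), x)
  from_opt <- function(z) ifelse(is_rate, 10^z, z)
  lo <- to_opt(bl); hi <- to_opt(bu)

  objective <- function(z) {
    r <- fit_residuals(datasets, spec, base_params, free, from_opt(z),
                       risc_mode = risc_mode)
    sum(r^2)
  }

  set.seed(seed)
  u <- lhs::randomLHS(n_starts, length(free))
  starts <- sweep(sweep(u, 2, hi - lo, `*`), 2, lo, `+`)

  recs <- vector("list", n_starts)
  best <- NULL
  for (i in seq_len(n_starts)) {
    z0 <- starts[i, ]
    f0 <- objective(z0)
    opt <- tryCatch(
      stats::nlminb(z0, objective, lower = lo, upper = hi,
                    control = list(rel.tol = 1e-10, x.tol = 1e-10)),
      error = function(e) NULL)
    recs[[i]] <- data.frame(
      start = i,
      objective_start = f0,
      objective = if (is.null(opt)) NA_real_ else opt$objective,
      convergence = if (is.null(opt)) NA_integer_ else opt$convergence,
      iterations = if (is.null(opt)) NA_integer_ else opt$iterations)
    if (!is.null(opt) &&
        (is.null(best) || opt$objective < best$objective)) best <- opt
  }
  if (is.null(best))
    stop("fit failure: no multi-start converged; per-start diagnostics ",
         "attached", call. = FALSE)
  est <- stats::setNames(from_opt(best$par), free)
  hit <- free[best$par <= lo + 1e-8 | best$par >= hi - 1e-8]

  if (length(free) > 1)
    check_identifiability(datasets, spec, base_params, free, est, risc_mode)

  structure(
    list(estimates = est, objective = best$objective,
         n_obs = sum(vapply(datasets, nrow, integer(1))),
         starts = do.call(rbind, recs), bounds = bounds[free],
         bounds_hit = hit, seed = seed, free = free,
         base_params = base_params, spec = spec, risc_mode = risc_mode,
         datasets = datasets),
    class = "lnp_fit")
}

# Jacobian-based correlation flag for weak identifiability.
check_identifiability <- function(datasets, spec, base_params, free, est,
                                  risc_mode, threshold = 0.99) {
  J <- residual_jacobian(datasets, spec, base_params, free, est, risc_mode)
  JtJ <- crossprod(J)
  cv <- tryCatch(solve(JtJ), error = function(e) NULL)
  if (is.null(cv)) {
    warning("identifiability: residual Jacobian is singular for {",
            paste(free, collapse = ", "), "}", call. = FALSE)
    return(invisible(NULL))
  }
  cm <- stats::cov2cor(cv)
  cm[upper.tri(cm, diag = TRUE)] <- 0
  if (any(abs(cm) > threshold)) {
    ij <- which(abs(cm) > threshold, arr.ind = TRUE)[1, ]
    warning(sprintf(
      "identifiability: parameters %s and %s are correlated (|r| > %.2f); ",
      free[ij[2]], free[ij[1]], threshold),
      "consider fixing one or adding another observable", call. = FALSE)
  }
  invisible(NULL)
}

residual_jacobian <- function(datasets, spec, base_params, free, est,
                              risc_mode, rel_step = 1e-5) {
  r0 <- fit_residuals(datasets, spec, base_params, free, est, risc_mode)
  vapply(seq_along(free), function(j) {
    h <- max(abs(est[j]) * rel_step, 1e-12)
    up <- dn <- est
    up[j] <- est[j] + h; dn[j] <- max(est[j] - h, 0)
    ru <- fit_residuals(datasets, spec, base_params, free, up, risc_mode)
    rd <- fit_residuals(datasets, spec, base_params, free, dn, risc_mode)
    (ru - rd) / (up[j] - dn[j])
  }, numeric(length(r0)))
}

#' @export
print.lnp_fit <- function(x, ...) {
  cat("<lnp_fit>\n")
  for (nm in names(x$estimates))
    cat(sprintf("  %-8s %.6g  [%.3g, %.3g]%s\n", nm, x$estimates[[nm]],
                x$bounds[[nm]][1], x$bounds[[nm]][2],
                if (nm %in% x$bounds_hit) "  (at bound)" else ""))
  cat(sprintf("  SSR = %.6g over %d observations, %d starts (seed %d)\n",
              x$objective, x$n_obs, nrow(x$starts), x$seed))
  invisible(x)
}

#' Parameter set implied by a fit
#'
#' @param fit an [fit_vehicle()] result.
#' @return The base parameter set with the fitted values substituted and
#'   tagged as \code{"fitted"}.
#' @export
fitted_parameters <- function(fit) {
  stopifnot(inherits(fit, "lnp_fit"))
  do.call(update_parameters,
          c(list(params = fit$base_params),
            as.list(fit$estimates), list(provenance = "fitted")))
}

#' Transfer vehicle and cargo constants into one predictive parameter set
#'
#' Vehicle-intrinsic constants (uptake \code{k1}, escape \code{k2} and its
#' onset \code{t_delay}) come from a fit of the vehicle; the cargo-specific
#' RISC-loading constant \code{k4} comes from a fit of the siRNA cargo.
#' Combining them predicts an untested vehicle x cargo pair without
#' further fitting.
#'
#' @param vehicle_fit an [fit_vehicle()] result whose free set is within
#'   \{k1, k2, t_delay\}.
#' @param cargo_fit an [fit_vehicle()] result supplying \code{k4}.
#' @param base an [parameter_set()] object for all remaining constants.
#' @return An \code{lnp_parameters} object ready for [simulate_model()].
#' @export
transfer_parameters <- function(vehicle_fit, cargo_fit, base) {
  stopifnot(inherits(vehicle_fit, "lnp_fit"), inherits(cargo_fit, "lnp_fit"),
            inherits(base, "lnp_parameters"))
  veh <- vehicle_fit$estimates[names(vehicle_fit$estimates) %in%
                                 c("k1", "k2", "t_delay")]
  crg <- cargo_fit$estimates[names(cargo_fit$estimates) %in% "k4"]
  overlap <- intersect(names(veh), names(cargo_fit$estimates))
  for (nm in overlap)
    if (abs(veh[[nm]] - cargo_fit$estimates[[nm]]) >
        1e-12 * max(abs(veh[[nm]]), 1e-300))
      stop("conflicting fitted values for ", nm,
           " between vehicle and cargo fits", call. = FALSE)
  do.call(update_parameters,
          c(list(params = base), as.list(c(veh, crg)),
            list(provenance = "fitted")))
}
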