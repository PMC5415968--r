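#' lnpkinetics: kinetic modeling of LNP-mediated siRNA delivery
#'
#' Simulation, fitting and sensitivity analysis for a five-species ODE
#' model of siRNA delivery by lipid nanoparticles: uptake, Heaviside-
#' delayed endosomal escape, RISC loading and catalytic mRNA cleavage.
#'
#' @useDynLib lnpkinetics, .registration = TRUE
#' @keywords internal
"_PACKAGE"

#' Avogadro's number (exact SI value)
#'
#' Fixed at the exact SI definition so that every unit conversion in the
#' package is bit-reproducible.
#'
#' @format A length-one numeric, 6.02214076e23 molecules per mole.
#' @export
AVOGADRO <- 6.02214076e23

#' Convert a molar concentration to molecules per cell
#'
#' The model's canonical concentration unit is molecules per cell. A dose
#' given in nanomolar in a compartment of known volume, shared among a known
#' number of cells, converts as
#' \code{conc * 1e-9 * volume * N_A / cells}.
#'
#' @param conc_nM concentration in nanomolar (>= 0).
#' @param volume_L compartment volume in liters (> 0).
#' @param cells number of cells sharing the compartment (>= 1).
#' @return Molecules per cell (numeric, vectorized over \code{conc_nM}).
#' @seealso [molecules_per_cell_to_nM()] for the exact inverse.
#' @examples
#' # 10 nM in the intracellular volume of a single cell
#' nM_to_molecules_per_cell(10, 1.4e-12, 1)
#' @export
nM_to_molecules_per_cell <- function(conc_nM, volume_L, cells) {
  if (!is.numeric(volume_L) || length(volume_L) != 1L || !is.finite(volume_L) ||
      volume_L <= 0)
    stop("`volume_L` must be a single positive number", call. = FALSE)
  if (!is.numeric(cells) || length(cells) != 1L || !is.finite(cells) ||
      cells < 1)
    stop("`cells` must be a single number >= 1", call. = FALSE)
  if (any(!is.finite(conc_nM)) || any(conc_nM < 0))
    stop("`conc_nM` must be finite and >= 0", call. = FALSE)
  conc_nM * 1e-9 * volume_L * AVOGADRO / cells
}

#' Convert molecules per cell back to nanomolar
#'
#' Exact inverse of [nM_to_molecules_per_cell()].
#'
#' @param n molecules per cell (>= 0).
#' @param volume_L compartment volume in liters (> 0).
#' @param cells number of cells (>= 1).
#' @return Concentration in nM.
#' @export
molecules_per_cell_to_nM <- function(n, volume_L, cells) {
  if (volume_L <= 0) stop("`volume_L` must be positive", call. = FALSE)
  if (cells < 1) stop("`cells` must be >= 1", call. = FALSE)
  n * cells / (1e-9 * volume_L * AVOGADRO)
}

#' Convert a bimolecular rate constant from L/(nM hr) to per-(molecules/cell)/hr
#'
#' Bimolecular constants (RISC loading \code{k4}, active-complex formation
#' \code{k6}) are tabulated in L/(nM hr). With species counted in molecules
#' per cell, the canonical second-order constant divides by the number of
#' molecules per cell equivalent to 1 nM in the reaction volume:
#' \code{k / (1e-9 * volume * N_A)}.
#'
#' @param k_nM_hr rate constant in L/(nM hr) (>= 0).
#' @param volume_L reaction-compartment volume in liters (> 0); for the
#'   cytoplasmic reactions this is the intracellular volume.
#' @return Rate constant in per-(molecules/cell) per hour.
#' @examples
#' bimolecular_rate_to_percell(0.001, 1.4e-12)  # canonical k4
#' @export
bimolecular_rate_to_percell <- function(k_nM_hr, volume_L) {
  if (!is.numeric(volume_L) || length(volume_L) != 1L || !is.finite(volume_L) ||
      volume_L <= 0)
    stop("`volume_L` must be a single positive number", call. = FALSE)
  if (any(!is.finite(k_nM_hr)) || any(k_nM_hr < 0))
    stop("`k_nM_hr` must be finite and >= 0", call. = FALSE)
  k_nM_hr / (1e-9 * volume_L * AVOGADRO)
}

#' Inverse of [bimolecular_rate_to_percell()]
#' @param k_percell rate constant in per-(molecules/cell)/hr.
#' @param volume_L reaction-compartment volume in liters.
#' @return Rate constant in L/(nM hr).
#' @export
percell_rate_to_bimolecular <- function(k_percell, volume_L) {
  if (volume_L <= 0) stop("`volume_L` must be positive", call. = FALSE)
  k_percell * (1e-9 * volume_L * AVOGADRO)
}

#' Experimental setup: compartments, cell count, dose and initial pools
#'
#' Bundles the physical constants that define the unit conversions and the
#' initial condition: compartment volumes, the number of cells sharing the
#' extracellular dose, the siRNA-LNP dose, and the initial free-RISC and
#' target-mRNA pools per cell. Defaults reproduce the reference in vitro
#' setup (10 nM dose in 3e-4 L over 10,000 cells; 1.4e-12 L cytoplasm;
#' 10,000 RISC and 100 mRNA copies per cell).
#'
#' @param extracellular_volume liters, > 0.
#' @param intracellular_volume liters, > 0.
#' @param cell_count cells sharing the extracellular compartment, >= 1.
#' @param dose_nM extracellular siRNA-LNP dose in nM, >= 0.
#' @param initial_risc free RISC copies per cell at t = 0, > 0.
#' @param initial_mrna target mRNA copies per cell at t = 0, > 0.
#' @return An object of class \code{lnp_experiment}.
#' @export
experiment_spec <- function(extracellular_volume = 3e-4,
                            intracellular_volume = 1.4e-12,
                            cell_count = 1e4,
                            dose_nM = 10,
                            initial_risc = 1e4,
                            initial_mrna = 100) {
  num1 <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
      stop(sprintf("`%s` must be a single finite number", nm), call. = FALSE)
    x
  }
  for (nm in c("extracellular_volume", "intracellular_volume", "cell_count",
               "initial_risc", "initial_mrna")) {
    v <- num1(get(nm), nm)
    if (v <= 0) stop(sprintf("`%s` must be strictly positive", nm),
                     call. = FALSE)
  }
  if (num1(dose_nM, "dose_nM") < 0)
    stop("`dose_nM` must be >= 0", call. = FALSE)
  structure(
    list(extracellular_volume = extracellular_volume,
         intracellular_volume = intracellular_volume,
         cell_count = cell_count,
         dose_nM = dose_nM,
         initial_risc = initial_risc,
         initial_mrna = initial_mrna),
    class = "lnp_experiment")
}

#' @export
print.lnp_experiment <- function(x, ...) {
  cat("<lnp_experiment>\n")
  cat(sprintf("  extracellular volume : %g L\n", x$extracellular_volume))
  cat(sprintf("  intracellular volume : %g L\n", x$intracellular_volume))
  cat(sprintf("  cells                : %g\n", x$cell_count))
  cat(sprintf("  dose                 : %g nM  (E0 = %.4g molecules/cell)\n",
              x$dose_nM, dose_molecules_per_cell(x)))
  cat(sprintf("  initial RISC / mRNA  : %g / %g copies per cell\n",
              x$initial_risc, x$initial_mrna))
  invisible(x)
}

#' Extracellular dose expressed in molecules per cell-equivalent
#'
#' The extracellular siRNA pool E is carried in the model as total
#' extracellular molecules divided by the cell count, so that the uptake
#' flux \code{k1 * E} is already in molecules per cell per hour.
#'
#' @param spec an [experiment_spec()] object.
#' @return E0 in molecules per cell-equivalent.
#' @export
dose_molecules_per_cell <- function(spec) {
  stopifnot(inherits(spec, "lnp_experiment"))
  nM_to_molecules_per_cell(spec$dose_nM, spec$extracellular_volume,
                           spec$cell_count)
}

PARAM_NAMES <- c(paste0("k", 1:9), "t_delay")
RATE_NAMES <- paste0("k", 1:9)

#' Model rate constants in canonical per-cell units
#'
#' Holds the nine rate constants plus the escape-onset delay. First-order
#' constants (k1, k2, k3, k5, k7, k9) are in 1/hr; the bimolecular constants
#' k4 (RISC loading) and k6 (active-complex formation) are in
#' per-(molecules/cell)/hr, i.e. already converted from the tabulated
#' L/(nM hr) form via [bimolecular_rate_to_percell()]; k8 (transcription) is
#' molecules/cell/hr. \code{t_delay} is the Heaviside onset time of
#' endosomal escape in hours (0 = no delay).
#'
#' Use [parameter_set_from_table()] when starting from table units, or
#' [vehicle_fixtures()] for the shipped vehicle panel.
#'
#' @param k1 uptake across the plasma membrane, 1/hr.
#' @param k2 endosomal escape / unpackaging, 1/hr.
#' @param k3 lysosomal degradation of endosomal cargo, 1/hr.
#' @param k4 siRNA loading onto RISC, per-(molecules/cell)/hr.
#' @param k5 cytoplasmic siRNA degradation, 1/hr.
#' @param k6 formation of the active RISC-mRNA complex,
#'   per-(molecules/cell)/hr.
#' @param k7 catalytic cleavage of target mRNA, 1/hr.
#' @param k8 mRNA transcription, molecules/cell/hr.
#' @param k9 mRNA degradation, 1/hr.
#' @param t_delay escape onset time, hr >= 0.
#' @param provenance named character vector tagging parameters as
#'   \code{"fixed"} or \code{"fitted"}; unnamed parameters default to
#'   \code{"fixed"}.
#' @return An object of class \code{lnp_parameters}.
#' @export
parameter_set <- function(k1, k2, k3, k4, k5, k6, k7, k8, k9,
                          t_delay = 0, provenance = NULL) {
  vals <- c(k1 = k1, k2 = k2, k3 = k3, k4 = k4, k5 = k5,
            k6 = k6, k7 = k7, k8 = k8, k9 = k9, t_delay = t_delay)
  if (any(!is.finite(vals)))
    stop("all parameters must be finite numbers", call. = FALSE)
  if (any(vals < 0))
    stop("rate constants and t_delay must be >= 0; offending: ",
         paste(names(vals)[vals < 0], collapse = ", "), call. = FALSE)
  prov <- stats::setNames(rep("fixed", length(PARAM_NAMES)), PARAM_NAMES)
  if (!is.null(provenance)) {
    bad <- setdiff(names(provenance), PARAM_NAMES)
    if (length(bad))
      stop("unknown provenance labels: ", paste(bad, collapse = ", "),
           call. = FALSE)
    if (!all(provenance %in% c("fixed", "fitted")))
      stop("provenance tags must be 'fixed' or 'fitted'", call. = FALSE)
    prov[names(provenance)] <- provenance
  }
  structure(list(values = vals, provenance = prov),
            class = "lnp_parameters")
}

#' @export
print.lnp_parameters <- function(x, ...) {
  cat("<lnp_parameters> (canonical per-cell units)\n")
  v <- x$values
  for (nm in names(v))
    cat(sprintf("  %-7s %-12.6g [%s]\n", nm, v[[nm]], x$provenance[[nm]]))
  invisible(x)
}

#' Build a parameter set from tabulated units
#'
#' Takes first-order constants in 1/hr, the bimolecular constants k4 and k6
#' in L/(nM hr), and converts the latter to per-(molecules/cell)/hr using
#' the cytoplasmic (intracellular) volume, where both reactions occur.
#'
#' @inheritParams parameter_set
#' @param k4_L_nM_hr,k6_L_nM_hr bimolecular constants in L/(nM hr).
#' @param intracellular_volume liters; reaction volume for k4 and k6.
#' @return An \code{lnp_parameters} object in canonical units.
#' @export
parameter_set_from_table <- function(k1, k2, k3, k4_L_nM_hr, k5, k6_L_nM_hr,
                                     k7, k8, k9, t_delay = 0,
                                     intracellular_volume = 1.4e-12,
                                     provenance = NULL) {
  parameter_set(
    k1 = k1, k2 = k2, k3 = k3,
    k4 = bimolecular_rate_to_percell(k4_L_nM_hr, intracellular_volume),
    k5 = k5,
    k6 = bimolecular_rate_to_percell(k6_L_nM_hr, intracellular_volume),
    k7 = k7, k8 = k8, k9 = k9, t_delay = t_delay, provenance = provenance)
}

#' Replace selected parameters, returning a new set
#'
#' @param params an \code{lnp_parameters} object.
#' @param ... named replacements among k1..k9 and t_delay (canonical units).
#' @param provenance tag applied to the replaced parameters
#'   (default \code{"fitted"} is convenient after estimation; use
#'   \code{"fixed"} for manual overrides).
#' @return A new \code{lnp_parameters} object.
#' @export
update_parameters <- function(params, ..., provenance = "fitted") {
  stopifnot(inherits(params, "lnp_parameters"))
  repl <- list(...)
  if (!length(repl)) return(params)
  bad <- setdiff(names(repl), PARAM_NAMES)
  if (length(bad) || is.null(names(repl)) || any(names(repl) == ""))
    stop("unknown parameter(s): ", paste(bad, collapse = ", "), call. = FALSE)
  v <- params$values
  v[names(repl)] <- unlist(repl)
  prov <- params$provenance
  prov[names(repl)] <- provenance
  do.call(parameter_set, c(as.list(v), list(provenance = prov)))
}

#' A named vehicle profile
#'
#' A delivery vehicle differs from the reference formulation only in its
#' vehicle-intrinsic constants (uptake k1, escape k2 and its onset delay,
#' lysosomal routing k3); an siRNA cargo differs only in its RISC-loading
#' constant k4.
#'
#' @param name nonempty label.
#' @param parameters an \code{lnp_parameters} object.
#' @param notes free-text annotation.
#' @return An object of class \code{lnp_vehicle}.
#' @export
vehicle_profile <- function(name, parameters, notes = "") {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("`name` must be a nonempty string", call. = FALSE)
  stopifnot(inherits(parameters, "lnp_parameters"))
  structure(list(name = name, parameters = parameters, notes = notes),
            class = "lnp_vehicle")
}

#' @export
print.lnp_vehicle <- function(x, ...) {
  cat(sprintf("<lnp_vehicle> %s\n", x$name))
  if (nzchar(x$notes)) cat(" ", x$notes, "\n")
  print(x$parameters)
  invisible(x)
}

CONFIG_SCHEMA_VERSION <- 1L
CONFIG_EXPERIMENT_KEYS <- c("extracellular_volume_L", "intracellular_volume_L",
                            "cell_count", "dose_nM", "initial_risc",
                            "initial_mrna")
CONFIG_PARAM_KEYS <- c("k1", "k2", "k3", "k4_L_nM_hr", "k5", "k6_L_nM_hr",
                       "k7", "k8", "k9")

#' Load an experiment + parameter configuration file
#'
#' Reads a flat key-value YAML document holding the experimental setup and
#' the rate constants in table units (first-order constants in 1/hr,
#' \code{k4_L_nM_hr}/\code{k6_L_nM_hr} in L/(nM hr), optional
#' \code{t_delay_hr}, required \code{schema_version}). Bimolecular constants
#' are converted to canonical per-cell units on load. A complete example is
#' shipped as \code{system.file("extdata", "lnp201_baseline.yaml",
#' package = "lnpkinetics")}.
#'
#' @param path path to a YAML configuration file.
#' @param unknown_keys \code{"warn"} (default) or \code{"error"} for keys
#'   outside the schema.
#' @return A list with elements \code{spec} ([experiment_spec()]) and
#'   \code{params} ([parameter_set()]).
#' @export
load_parameters <- function(path, unknown_keys = c("warn", "error")) {
  unknown_keys <- match.arg(unknown_keys)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$schema_version))
    stop("configuration schema error: missing required key 'schema_version'",
         call. = FALSE)
  required <- c(CONFIG_EXPERIMENT_KEYS, CONFIG_PARAM_KEYS)
  missing <- setdiff(required, names(cfg))
  if (length(missing))
    stop("configuration schema error: missing required key(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  known <- c("schema_version", required, "t_delay_hr", "label")
  extra <- setdiff(names(cfg), known)
  if (length(extra)) {
    msg <- paste0("unknown configuration key(s): ",
                  paste(extra, collapse = ", "))
    if (unknown_keys == "error") stop(msg, call. = FALSE) else warning(msg,
      call. = FALSE)
  }
  num <- vapply(cfg[required], function(x) as.numeric(x)[1], numeric(1))
  if (any(!is.finite(num)))
    stop("configuration validation error: non-numeric value for ",
         paste(required[!is.finite(num)], collapse = ", "), call. = FALSE)
  neg <- required[num < 0]
  if (length(neg))
    stop("configuration validation error: negative value for ",
         paste(neg, collapse = ", "), call. = FALSE)
  spec <- experiment_spec(
    extracellular_volume = num[["extracellular_volume_L"]],
    intracellular_volume = num[["intracellular_volume_L"]],
    cell_count = num[["cell_count"]],
    dose_nM = num[["dose_nM"]],
    initial_risc = num[["initial_risc"]],
    initial_mrna = num[["initial_mrna"]])
  t_delay <- if (is.null(cfg$t_delay_hr)) 0 else as.numeric(cfg$t_delay_hr)
  if (!is.finite(t_delay) || t_delay < 0)
    stop("configuration validation error: t_delay_hr must be finite and >= 0",
         call. = FALSE)
  params <- parameter_set_from_table(
    k1 = num[["k1"]], k2 = num[["k2"]], k3 = num[["k3"]],
    k4_L_nM_hr = num[["k4_L_nM_hr"]], k5 = num[["k5"]],
    k6_L_nM_hr = num[["k6_L_nM_hr"]], k7 = num[["k7"]],
    k8 = num[["k8"]], k9 = num[["k9"]], t_delay = t_delay,
    intracellular_volume = spec$intracellular_volume)
  list(spec = spec, params = params)
}

#' Serialize an experiment + parameter pair back to a configuration file
#'
#' Writes the same flat YAML dialect read by [load_parameters()], with
#' bimolecular constants converted back to L/(nM hr). A written file
#' re-loads to a numerically identical configuration.
#'
#' @param spec an [experiment_spec()] object.
#' @param params an [parameter_set()] object (canonical units).
#' @param path output file path.
#' @param label optional free-text label stored in the file.
#' @return \code{path}, invisibly.
#' @export
write_parameters <- function(spec, params, path, label = NULL) {
  stopifnot(inherits(spec, "lnp_experiment"), inherits(params,
                                                       "lnp_parameters"))
  v <- params$values
  out <- list(
    schema_version = CONFIG_SCHEMA_VERSION,
    extracellular_volume_L = spec$extracellular_volume,
    intracellular_volume_L = spec$intracellular_volume,
    cell_count = spec$cell_count,
    dose_nM = spec$dose_nM,
    initial_risc = spec$initial_risc,
    initial_mrna = spec$initial_mrna,
    k1 = v[["k1"]], k2 = v[["k2"]], k3 = v[["k3"]],
    k4_L_nM_hr = percell_rate_to_bimolecular(v[["k4"]],
                                             spec$intracellular_volume),
    k5 = v[["k5"]],
    k6_L_nM_hr = percell_rate_to_bimolecular(v[["k6"]],
                                             spec$intracellular_volume),
    k7 = v[["k7"]], k8 = v[["k8"]], k9 = v[["k9"]],
    t_delay_hr = v[["t_delay"]])
  if (!is.null(label)) out$label <- label
  yaml::write_yaml(out, path, precision = 17L)
  invisible(path)
}
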