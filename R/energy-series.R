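#' @keywords internal
"_PACKAGE"

KJ_PER_KCAL <- 4.184

LEG_LABELS <- c("complex", "solvent", "receptor", "ligand")
ENERGY_UNITS <- c("kJ/mol", "kcal/mol")

#' Convert an energy value to kcal/mol
#'
#' The thermochemical calorie defines the conversion: 1 kcal/mol is exactly
#' 4.184 kJ/mol. Values already in kcal/mol are returned unchanged.
#'
#' @param value numeric vector of energies.
#' @param from_units `"kJ/mol"` or `"kcal/mol"`.
#' @return numeric vector in kcal/mol.
#' @examples
#' convert_energy_units(4.184, "kJ/mol")  # 1
#' @export
convert_energy_units <- function(value, from_units) {
  if (!is.character(from_units) || length(from_units) != 1L ||
      !from_units %in% ENERGY_UNITS) {
    stop("unknown energy unit: ", deparse(from_units),
         " (expected one of ", paste(ENERGY_UNITS, collapse = ", "), ")")
  }
  if (from_units == "kJ/mol") value / KJ_PER_KCAL else value
}

#' Construct an energy time series for one simulation leg
#'
#' One leg's potential-energy trace: the samples whose time average enters
#' the direct-method enthalpy as one of <E>_complex, <E>_solvent,
#' <E>_receptor, <E>_ligand. Values are stored in kcal/mol regardless of the
#' input unit.
#'
#' @param values numeric vector of potential energies (finite, length >= 1).
#' @param dt frame spacing in ps (> 0).
#' @param leg one of `"complex"`, `"solvent"`, `"receptor"`, `"ligand"`.
#' @param replica_id non-negative integer replica index.
#' @param system_id free-text complex identifier (e.g. a PDB code).
#' @param units `"kJ/mol"` or `"kcal/mol"`; unit of `values` as supplied.
#' @return an `energy_series` object (values always in kcal/mol;
#'   `units_original` records the input unit).
#' @export
energy_series <- function(values, dt, leg, replica_id = 0L,
                          system_id = "unknown", units = "kcal/mol") {
  values <- as.numeric(values)
  if (length(values) < 1L) stop("energy series must contain at least 1 value")
  if (!all(is.finite(values))) stop("energy series contains non-finite values")
  dt <- as.numeric(dt)
  if (length(dt) != 1L || !is.finite(dt) || dt <= 0) stop("dt must be > 0")
  leg <- match.arg(leg, LEG_LABELS)
  replica_id <- as.integer(replica_id)
  if (is.na(replica_id) || replica_id < 0L) stop("replica_id must be >= 0")
  structure(
    list(values = convert_energy_units(values, units),
         dt = dt, leg = leg, replica_id = replica_id,
         system_id = as.character(system_id), units_original = units),
    class = "energy_series")
}

#' @export
print.energy_series <- function(x, ...) {
  cat(sprintf("<energy_series> leg=%s system=%s replica=%d n=%d dt=%g ps\n",
              x$leg, x$system_id, x$replica_id, length(x$values), x$dt))
  cat(sprintf("  mean = %.4f kcal/mol (original units: %s)\n",
              mean(x$values), x$units_original))
  invisible(x)
}

#' @export
length.energy_series <- function(x) length(x$values)

#' @export
mean.energy_series <- function(x, ...) mean(x$values, ...)

is_energy_series <- function(x) inherits(x, "energy_series")

stopifnot_same_leg <- function(replicas) {
  if (length(replicas) < 1L) stop("need at least one replica")
  ok <- vapply(replicas, is_energy_series, logical(1))
  if (!all(ok)) stop("all replicas must be energy_series objects")
  legs <- vapply(replicas, function(r) r$leg, character(1))
  if (length(unique(legs)) != 1L) {
    stop("mixed legs in replica set: ", paste(unique(legs), collapse = ", "))
  }
  dts <- vapply(replicas, function(r) r$dt, numeric(1))
  if (diff(range(dts)) > 1e-9 * max(dts)) {
    stop("replicas disagree on frame spacing dt")
  }
  invisible(legs[1L])
}
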