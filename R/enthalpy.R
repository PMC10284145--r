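# Direct-method binding enthalpy: dH = <E>_complex + <E>_solvent
# - <E>_receptor - <E>_ligand, with atom counts exactly balanced between the
# bound side (complex + solvent) and the unbound side (receptor + ligand).
# The pressure-volume contribution is negligible at these conditions and is
# omitted by design (no option).

#' Build an atom-balance sheet
#'
#' @param counts data.frame with columns `leg`, `species`, `count`
#'   (non-negative integers); one row per leg x species.
#' @return an `atom_balance_sheet` data.frame.
#' @export
atom_balance_sheet <- function(counts) {
  stopifnot(all(c("leg", "species", "count") %in% names(counts)))
  if (!all(counts$leg %in% LEG_LABELS)) {
    stop("unknown leg label(s): ",
         paste(setdiff(unique(counts$leg), LEG_LABELS), collapse = ", "))
  }
  if (any(counts$count < 0)) stop("atom counts must be >= 0")
  missing <- setdiff(LEG_LABELS, unique(counts$leg))
  if (length(missing) > 0L) {
    stop("atom-balance sheet missing leg(s): ",
         paste(missing, collapse = ", "))
  }
  out <- counts[, c("leg", "species", "count")]
  class(out) <- c("atom_balance_sheet", class(out))
  out
}

#' Check bound/unbound atom balance
#'
#' The direct method is only valid when, species by species,
#' `count(complex) + count(solvent) == count(receptor) + count(ligand)`
#' (excess solvent is deleted at setup time to enforce this). Any imbalance
#' silently shifts the enthalpy by the per-atom mean energy of the excess
#' species, so the CLI treats a failed check as a hard gate.
#'
#' @param sheet an [atom_balance_sheet()].
#' @return list with `pass` (logical) and `deficits` (data.frame
#'   `species`, `bound`, `unbound`, `deficit` where `deficit = bound -
#'   unbound`).
#' @export
check_atom_balance <- function(sheet) {
  sheet <- atom_balance_sheet(sheet)
  species <- sort(unique(sheet$species))
  tot <- function(leg, sp) {
    sum(sheet$count[sheet$leg == leg & sheet$species == sp])
  }
  bound <- vapply(species, function(sp) tot("complex", sp) + tot("solvent", sp),
                  numeric(1))
  unbound <- vapply(species, function(sp) tot("receptor", sp) + tot("ligand", sp),
                    numeric(1))
  deficits <- data.frame(species = species, bound = bound, unbound = unbound,
                         deficit = bound - unbound, row.names = NULL,
                         stringsAsFactors = FALSE)
  list(pass = all(deficits$deficit == 0), deficits = deficits)
}

#' Combine four leg estimates into a binding enthalpy
#'
#' `dH = mean(complex) + mean(solvent) - mean(receptor) - mean(ligand)`;
#' the SEM is the quadrature of the four leg SEMs (legs come from separate
#' simulations, hence independent errors). Inputs may arrive in any order:
#' only the `leg` tags matter.
#'
#' @param ... exactly four [leg_estimate()]s (or [estimate_leg()] results),
#'   one per leg, in any order; alternatively a single list of four.
#' @param condition provenance label: `"all"`, `"ZA1"`, `"ZA2"` or
#'   `"combined"`.
#' @param system_id complex identifier.
#' @return an `enthalpy_estimate` list: `dH`, `sem`, `legs`, `condition`,
#'   `system_id`.
#' @export
combine_legs <- function(..., condition = "all", system_id = "unknown") {
  legs <- list(...)
  if (length(legs) == 1L && !inherits(legs[[1]], "leg_estimate")) {
    legs <- legs[[1]]
  }
  if (length(legs) != 4L ||
      !all(vapply(legs, inherits, logical(1), "leg_estimate"))) {
    stop("combine_legs needs exactly four leg_estimate objects")
  }
  labels <- vapply(legs, `[[`, character(1), "leg")
  if (anyDuplicated(labels) || !setequal(labels, LEG_LABELS)) {
    stop("need exactly one estimate per leg; got: ",
         paste(labels, collapse = ", "))
  }
  names(legs) <- labels
  condition <- match.arg(condition, c("all", "ZA1", "ZA2", "combined"))
  dH <- legs$complex$mean + legs$solvent$mean -
    legs$receptor$mean - legs$ligand$mean
  sem <- sqrt(sum(vapply(legs, `[[`, numeric(1), "sem")^2))
  structure(list(dH = dH, sem = sem, legs = legs[LEG_LABELS],
                 condition = condition, system_id = system_id),
            class = "enthalpy_estimate")
}

#' @export
print.enthalpy_estimate <- function(x, ...) {
  cat(sprintf("<enthalpy_estimate> %s [%s]: dH = %.2f +/- %.2f kcal/mol\n",
              x$system_id, x$condition, x$dH, x$sem))
  invisible(x)
}

#' Absolute deviation of a prediction from experiment
#'
#' @param estimate an `enthalpy_estimate` (or anything with `dH` and
#'   `system_id`).
#' @param experiment a [thermo_record()] row (matching `system_id`).
#' @return `|dH_pred - dH_exp|` in kcal/mol (unrounded).
#' @export
absolute_deviation <- function(estimate, experiment) {
  exp_row <- as.list(experiment)
  if (!identical(as.character(estimate$system_id),
                 as.character(exp_row$system_id))) {
    stop(sprintf("system_id mismatch: prediction '%s' vs experiment '%s'",
                 estimate$system_id, exp_row$system_id))
  }
  abs(estimate$dH - exp_row$dH)
}
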