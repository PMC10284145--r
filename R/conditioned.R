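# Conditioning energy series on loop state. Blocking never crosses a state
# boundary: concatenating non-contiguous frames would fabricate spurious
# decorrelation, so each contiguous single-state segment is blocked on its
# own and segment means are pooled weighted by length.

#' Extract the contiguous segments of one state from an energy series
#'
#' @param series an [energy_series()].
#' @param trace a frame-aligned [state_trace()].
#' @param state `"ZA1"` or `"ZA2"`.
#' @return a `conditioned_series` list: `parent` (provenance), `state`,
#'   `segments` (data.frame `start`, `end`, 1-based inclusive), and
#'   `values` (list of per-segment numeric vectors). UNASSIGNED frames
#'   break runs and are excluded. The segment list may be empty.
#' @export
condition_series <- function(series, trace, state = c("ZA1", "ZA2")) {
  state <- match.arg(state)
  stopifnot(is_energy_series(series), inherits(trace, "state_trace"))
  if (length(series$values) != length(trace$labels)) {
    stop("series and trace are not frame-aligned (",
         length(series$values), " vs ", length(trace$labels), " frames)")
  }
  r <- rle(trace$labels == state)
  ends <- cumsum(r$lengths)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  keep <- which(r$values)
  segments <- data.frame(start = starts[keep], end = ends[keep])
  structure(list(
    parent = list(leg = series$leg, replica_id = series$replica_id,
                  system_id = series$system_id, dt = series$dt),
    state = state, segments = segments,
    values = lapply(seq_len(nrow(segments)), function(i) {
      series$values[segments$start[i]:segments$end[i]]
    })),
    class = "conditioned_series")
}

# (mean, sem) of one segment; short segments fall back to the naive SEM
# since they admit no blocking levels (sem 0 for a single frame).
segment_estimate <- function(x, min_blocks) {
  if (length(x) >= min_blocks) {
    sel <- select_sem(blocking_curve(x, min_blocks))
    c(mean = mean(x), sem = sel$sem, n = length(x))
  } else {
    s <- if (length(x) > 1L) stats::sd(x) / sqrt(length(x)) else 0
    c(mean = mean(x), sem = s, n = length(x))
  }
}

# Pool segment estimates weighted by length: mean = sum w_i m_i,
# sem = sqrt(sum (w_i sem_i)^2) with w_i = n_i / N.
pool_segments <- function(seg_values, min_blocks) {
  ests <- vapply(seg_values, segment_estimate, numeric(3), min_blocks)
  w <- ests["n", ] / sum(ests["n", ])
  list(mean = sum(w * ests["mean", ]),
       sem = sqrt(sum((w * ests["sem", ])^2)),
       n = sum(ests["n", ]))
}

#' Potential-energy difference between the two loop states
#'
#' `dE = <E | ZA1> - <E | ZA2>`, each conditional mean estimated by
#' segment-wise blocking pooled over segments, with the SEM of the
#' difference given by quadrature of the two state SEMs.
#'
#' @param series an [energy_series()] (or list of replicas with a matching
#'   list of traces).
#' @param trace frame-aligned [state_trace()] (or list).
#' @param min_blocks blocking floor, see [blocking_curve()].
#' @return list with `dE`, `sem`, and per-state `mean`, `sem`, `n_frames`.
#' @export
state_energy_difference <- function(series, trace, min_blocks = 8L) {
  if (is_energy_series(series)) { series <- list(series); trace <- list(trace) }
  per_state <- lapply(c(ZA1 = "ZA1", ZA2 = "ZA2"), function(st) {
    segs <- list()
    for (i in seq_along(series)) {
      segs <- c(segs, condition_series(series[[i]], trace[[i]], st)$values)
    }
    if (length(segs) == 0L) {
      stop("state ", st, " is absent from the trace; ",
           "cannot form a conditional mean")
    }
    pool_segments(segs, min_blocks)
  })
  list(dE = per_state$ZA1$mean - per_state$ZA2$mean,
       sem = sqrt(per_state$ZA1$sem^2 + per_state$ZA2$sem^2),
       ZA1 = per_state$ZA1, ZA2 = per_state$ZA2)
}

# Replica-level conditioned estimate for one leg: per replica, pool that
# replica's single-state segments; across replicas, reuse the unconditioned
# per-replica combination rule (unweighted mean; max of quadrature and
# replica scatter). Replicas never visiting the state are dropped.
conditioned_leg_estimate <- function(replicas, traces, state, min_blocks) {
  leg <- stopifnot_same_leg(replicas)
  if (length(traces) != length(replicas)) {
    stop("need one state trace per complex replica")
  }
  per <- list()
  dropped <- 0L
  for (i in seq_along(replicas)) {
    cs <- condition_series(replicas[[i]], traces[[i]], state)
    if (length(cs$values) == 0L) { dropped <- dropped + 1L; next }
    per[[length(per) + 1L]] <- pool_segments(cs$values, min_blocks)
  }
  if (length(per) == 0L) {
    stop("state ", state, " is empty in every replica")
  }
  if (dropped > 0L) {
    bc_log("WARN", dropped, " replica(s) never visit ", state,
           " and were dropped from the conditional estimate")
  }
  means <- vapply(per, `[[`, numeric(1), "mean")
  sems <- vapply(per, `[[`, numeric(1), "sem")
  R <- length(per)
  within <- sqrt(sum(sems^2)) / R
  between <- if (R > 1L) stats::sd(means) / sqrt(R) else 0
  leg_estimate(leg, mean = mean(means), sem = max(within, between),
               n_replicas = R,
               n_frames_total = sum(vapply(per, `[[`, numeric(1), "n")),
               selection_rule = sprintf(
                 "conditioned on %s; segment-pooled per replica; max(%.4g, %.4g)",
                 state, within, between))
}

#' State-conditioned binding enthalpy
#'
#' Restricts the complex leg to frames in the requested loop state before
#' estimation; the solvent, receptor and ligand legs always use all frames
#' (the apo-state conformational energy difference is small relative to its
#' error; receptor-leg conditioning is available via `condition_receptor`
#' for sensitivity analysis).
#'
#' Conditions: `"all"` uses every frame; `"ZA1"`/`"ZA2"` restrict the
#' complex leg to that state's contiguous segments; `"combined"` pools all
#' supplied replicas (runs started in either state) and estimates them as
#' one set — computationally identical to `"all"` on the union, recorded
#' distinctly in provenance.
#'
#' @param legs named list with elements `complex`, `solvent`, `receptor`,
#'   `ligand`, each a list of [energy_series()] replicas.
#' @param traces list of [state_trace()]s, one per complex replica (may be
#'   `NULL` for `condition = "all"`/`"combined"`).
#' @param condition `"all"`, `"ZA1"`, `"ZA2"` or `"combined"`.
#' @param min_blocks blocking floor.
#' @param system_id complex identifier.
#' @param condition_receptor also condition the receptor leg (requires
#'   `receptor_traces`).
#' @param receptor_traces traces for the receptor replicas.
#' @return an `enthalpy_estimate` (see [combine_legs()]).
#' @export
conditional_enthalpy <- function(legs, traces = NULL,
                                 condition = c("all", "ZA1", "ZA2", "combined"),
                                 min_blocks = 8L, system_id = "unknown",
                                 condition_receptor = FALSE,
                                 receptor_traces = NULL) {
  condition <- match.arg(condition)
  if (!all(LEG_LABELS %in% names(legs))) {
    stop("legs must be a named list with complex, solvent, receptor, ligand")
  }
  est <- list()
  for (leg in LEG_LABELS) {
    conditioned <- (condition %in% c("ZA1", "ZA2")) &&
      (leg == "complex" || (leg == "receptor" && condition_receptor))
    est[[leg]] <- if (conditioned) {
      tr <- if (leg == "complex") traces else receptor_traces
      if (is.null(tr)) stop("conditioning the ", leg,
                            " leg requires its state traces")
      conditioned_leg_estimate(legs[[leg]], tr, condition, min_blocks)
    } else {
      estimate_leg(legs[[leg]], min_blocks = min_blocks)
    }
  }
  combine_legs(est$complex, est$solvent, est$receptor, est$ligand,
               condition = condition, system_id = system_id)
}

#' Infer the entropic term and check thermodynamic consistency
#'
#' `TdS` is computed as `dH - dG`; when the record stores a `TdS`, the row
#' is flagged inconsistent if the stored and computed values differ by more
#' than `tolerance` (default 0.02 kcal/mol, absorbing two-decimal
#' rounding). Inconsistent rows are flagged, never corrected: a printed
#' sign error in a source table must stay visible.
#'
#' @param record a [thermo_record()]-shaped data.frame (any number of
#'   rows), or a list/row with at least `dH` and `dG`.
#' @param tolerance kcal/mol.
#' @return data.frame with `system_id`, `dH`, `dG`, `TdS_stored` (`NA` if
#'   absent), `TdS_computed`, `consistent`.
#' @export
infer_entropy_and_check <- function(record, tolerance = 0.02) {
  df <- as.data.frame(record, stringsAsFactors = FALSE)
  if (!all(c("dH", "dG") %in% names(df))) stop("need dH and dG")
  stored <- if ("TdS" %in% names(df)) df$TdS else rep(NA_real_, nrow(df))
  computed <- df$dH - df$dG
  data.frame(
    system_id = if ("system_id" %in% names(df)) df$system_id else
      NA_character_,
    dH = df$dH, dG = df$dG, TdS_stored = stored, TdS_computed = computed,
    consistent = is.na(stored) | abs(stored - computed) <= tolerance,
    stringsAsFactors = FALSE)
}
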