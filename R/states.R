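# Per-frame loop-state assignment (ZA1 crystal-like vs ZA2 alternative) from
# hinge dihedrals or loop RMSD, dwell-time smoothing, and transition
# statistics.

STATE_LABELS <- c("ZA1", "ZA2", "UNASSIGNED")

#' Construct a per-frame state trace
#'
#' @param labels character vector over `"ZA1"`, `"ZA2"`, `"UNASSIGNED"`.
#' @param dt frame spacing (ps).
#' @return a `state_trace` object.
#' @export
state_trace <- function(labels, dt = 1) {
  labels <- as.character(labels)
  if (length(labels) < 1L) stop("state trace must be non-empty")
  bad <- setdiff(unique(labels), STATE_LABELS)
  if (length(bad) > 0L) stop("unknown state label(s): ",
                             paste(bad, collapse = ", "))
  structure(list(labels = labels, dt = dt), class = "state_trace")
}

#' @export
length.state_trace <- function(x) length(x$labels)

#' @export
print.state_trace <- function(x, ...) {
  tb <- table(factor(x$labels, levels = STATE_LABELS))
  cat(sprintf("<state_trace> %d frames (dt = %g ps): ZA1 %d, ZA2 %d, UNASSIGNED %d\n",
              length(x$labels), x$dt, tb[["ZA1"]], tb[["ZA2"]],
              tb[["UNASSIGNED"]]))
  invisible(x)
}

#' Assign loop states from the two hinge dihedrals
#'
#' The hinge torsions move between well-separated modal values across the
#' transition (psi: 50 to -40 degrees; phi: -150 to -60 degrees). The
#' default cuts are the midpoints of those modes: a frame is ZA1 iff
#' `psi > psi_cut` and `phi < phi_cut`; ZA2 iff `psi <= psi_cut` and
#' `phi >= phi_cut`; frames where the two hinges disagree are UNASSIGNED.
#' Classification is per-frame; no circular averaging is done.
#'
#' @param psi,phi frame-aligned [dihedral_series()] of the two hinges.
#' @param psi_cut,phi_cut thresholds in degrees.
#' @return a [state_trace()].
#' @export
assign_states_dihedral <- function(psi, phi, psi_cut = 5, phi_cut = -105) {
  pa <- if (inherits(psi, "dihedral_series")) psi$angles else as.numeric(psi)
  fa <- if (inherits(phi, "dihedral_series")) phi$angles else as.numeric(phi)
  if (length(pa) != length(fa)) {
    stop("psi and phi series are not frame-aligned (",
         length(pa), " vs ", length(fa), " frames)")
  }
  dt <- if (inherits(psi, "dihedral_series")) psi$dt else 1
  labels <- rep("UNASSIGNED", length(pa))
  labels[pa > psi_cut & fa < phi_cut] <- "ZA1"
  labels[pa <= psi_cut & fa >= phi_cut] <- "ZA2"
  state_trace(labels, dt = dt)
}

#' Assign loop states from a loop-RMSD series (cross-check classifier)
#'
#' ZA2 iff the loop backbone RMSD to the crystal-like reference exceeds
#' `rmsd_cut` (default 2.5 Angstrom); otherwise ZA1. Provided as an
#' independent cross-check of the dihedral classifier.
#'
#' @param rmsd numeric per-frame RMSD series (Angstrom).
#' @param rmsd_cut threshold (Angstrom).
#' @param dt frame spacing (ps).
#' @return a [state_trace()].
#' @export
assign_states_rmsd <- function(rmsd, rmsd_cut = 2.5, dt = 1) {
  state_trace(ifelse(rmsd > rmsd_cut, "ZA2", "ZA1"), dt = dt)
}

#' Agreement rate between two classifiers
#'
#' @param a,b frame-aligned [state_trace()]s.
#' @return fraction of frames with identical labels.
#' @export
state_agreement <- function(a, b) {
  if (length(a$labels) != length(b$labels)) stop("traces not frame-aligned")
  mean(a$labels == b$labels)
}

#' Smooth a state trace by a minimum dwell time
#'
#' Runs shorter than `min_dwell` frames inherit the previous persistent
#' state (emission flicker suppression); the initial run always stands.
#'
#' @param trace a [state_trace()].
#' @param min_dwell minimum run length in frames (>= 1).
#' @return a smoothed [state_trace()].
#' @export
smooth_state_trace <- function(trace, min_dwell = 5L) {
  if (min_dwell < 1L) stop("min_dwell must be >= 1")
  r <- rle(trace$labels)
  current <- r$values[1]
  for (i in seq_along(r$values)[-1]) {
    if (r$lengths[i] < min_dwell) {
      r$values[i] <- current
    } else {
      current <- r$values[i]
    }
  }
  state_trace(inverse.rle(r), dt = trace$dt)
}

#' Occupancy and transition statistics of a state trace
#'
#' A transition is registered only when the new state persists for at least
#' `min_dwell` frames (shorter flickers inherit the previous state, via
#' [smooth_state_trace()]). Occupancies are fractions of assigned frames;
#' times are reported in ns using the trace's frame spacing, with a
#' transition timed at its first frame in the new state.
#'
#' @param trace a [state_trace()].
#' @param min_dwell minimum dwell in frames.
#' @return list with `occupancy` (named ZA1/ZA2 fractions of assigned
#'   frames), `transitions` (data.frame `frame` 0-based, `time_ns`, `from`,
#'   `to`), `first_za1_to_za2_ns` (`NA` if none), `n_forward`, `n_reverse`
#'   (ZA2 -> ZA1 event count), and the smoothed trace.
#' @export
transition_stats <- function(trace, min_dwell = 5L) {
  sm <- smooth_state_trace(trace, min_dwell)
  assigned <- sm$labels[sm$labels != "UNASSIGNED"]
  if (length(assigned) == 0L) {
    stop("occupancy undefined: trace has no assigned frames")
  }
  occupancy <- c(ZA1 = mean(assigned == "ZA1"),
                 ZA2 = mean(assigned == "ZA2"))

  r <- rle(sm$labels)
  ends <- cumsum(r$lengths)
  starts0 <- c(0L, ends[-length(ends)])  # 0-based first frame of each run
  keep <- r$values != "UNASSIGNED"
  av <- r$values[keep]; as0 <- starts0[keep]
  chg <- which(av[-1] != av[-length(av)]) + 1L  # runs that change state
  trans <- data.frame(frame = as0[chg], time_ns = as0[chg] * sm$dt / 1000,
                      from = av[chg - 1L], to = av[chg],
                      stringsAsFactors = FALSE)
  fwd <- trans[trans$from == "ZA1" & trans$to == "ZA2", , drop = FALSE]
  rev <- trans[trans$from == "ZA2" & trans$to == "ZA1", , drop = FALSE]
  list(occupancy = occupancy, transitions = trans,
       first_za1_to_za2_ns = if (nrow(fwd) > 0L) fwd$time_ns[1] else NA_real_,
       n_forward = nrow(fwd), n_reverse = nrow(rev), smoothed = sm)
}

#' Mean first forward-transition time over replicas
#'
#' @param traces list of [state_trace()]s (one per replica).
#' @param min_dwell minimum dwell in frames.
#' @return list with `mean_ns`, `se_ns`, `n_transitioned` (replicas showing
#'   a ZA1 -> ZA2 transition), `n_replicas`, and the per-replica times.
#' @export
mean_transition_time <- function(traces, min_dwell = 5L) {
  times <- vapply(traces, function(tr) {
    transition_stats(tr, min_dwell)$first_za1_to_za2_ns
  }, numeric(1))
  obs <- times[!is.na(times)]
  list(mean_ns = if (length(obs) > 0L) mean(obs) else NA_real_,
       se_ns = if (length(obs) > 1L) stats::sd(obs) / sqrt(length(obs))
               else NA_real_,
       n_transitioned = length(obs), n_replicas = length(times),
       times_ns = times)
}
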