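# Least-squares superposition and derived observables: RMSD series, RMSF,
# backbone dihedrals, atom-pair distances.

#' Kabsch superposition of two coordinate sets
#'
#' Finds the proper rotation and translation minimizing the RMSD of
#' `mobile` onto `reference` over index-matched fit atoms, via SVD of the
#' covariance matrix with the determinant correction that excludes
#' reflections.
#'
#' @param reference,mobile numeric `[n, 3]` matrices (index-matched).
#' @param fit_selection indices of the atoms to superpose on (default all).
#' @return list with `rotation` (3x3, applied as `x %*% rotation`),
#'   `translation` (length 3), and `rmsd` (Angstrom, over the fit atoms).
#'   The fitted mobile coordinates are
#'   `sweep(mobile %*% rotation, 2, translation, "+")`.
#' @export
kabsch_rmsd <- function(reference, mobile, fit_selection = NULL) {
  reference <- as.matrix(reference); mobile <- as.matrix(mobile)
  if (!all(dim(reference) == dim(mobile)) || ncol(reference) != 3L) {
    stop("reference and mobile must be index-matched [n, 3] matrices")
  }
  idx <- if (is.null(fit_selection)) seq_len(nrow(reference)) else
    as.integer(fit_selection)
  if (length(idx) < 3L) stop("degenerate fit: need >= 3 fit atoms")
  P <- mobile[idx, , drop = FALSE]
  Q <- reference[idx, , drop = FALSE]
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  if (qr(Pc)$rank < 2L) stop("degenerate fit: fit atoms are collinear")
  H <- crossprod(Pc, Qc)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)  # x %*% R rotates mobile
  translation <- cq - as.numeric(cp %*% R)
  fitted <- sweep(Pc %*% R, 2, cq, "+")
  rmsd <- sqrt(mean(rowSums((fitted - Q)^2)))
  list(rotation = R, translation = translation, rmsd = rmsd)
}

apply_fit <- function(x, fit) sweep(x %*% fit$rotation, 2, fit$translation, "+")

rmsd_plain <- function(a, b) sqrt(mean(rowSums((a - b)^2)))

#' Per-frame RMSD of a region after global superposition
#'
#' Each frame is superposed onto the reference using `fit_selection` (e.g.
#' the whole-protein backbone); the RMSD is then measured over
#' `measure_selection` (e.g. the binding-site loop backbone) without
#' refitting, so genuine loop motion is not absorbed by the fit.
#'
#' @param traj a [trajectory_coords()].
#' @param reference `[n_atoms, 3]` coordinate set on the same roster
#'   (default: first frame).
#' @param fit_selection,measure_selection selections (see
#'   [resolve_selection()]).
#' @param pairwise if `TRUE`, return the symmetric frame-by-frame RMSD
#'   matrix (each pair fitted on `fit_selection`, measured on
#'   `measure_selection`) instead of the per-frame series.
#' @return numeric vector of per-frame RMSDs (Angstrom), or a matrix when
#'   `pairwise = TRUE`.
#' @export
loop_rmsd_series <- function(traj, reference = NULL,
                             fit_selection = "backbone",
                             measure_selection = "resid 76-106 and backbone",
                             pairwise = FALSE) {
  fit_idx <- resolve_selection(traj, fit_selection)
  mea_idx <- resolve_selection(traj, measure_selection)
  F <- n_frames(traj)
  if (pairwise) {
    M <- matrix(0, F, F)
    for (i in seq_len(F)) {
      ref_i <- frame_coords(traj, i)
      for (j in seq_len(F)) {
        if (j <= i) next
        fit <- kabsch_rmsd(ref_i, frame_coords(traj, j), fit_idx)
        fitted <- apply_fit(frame_coords(traj, j), fit)
        M[i, j] <- M[j, i] <- rmsd_plain(fitted[mea_idx, , drop = FALSE],
                                         ref_i[mea_idx, , drop = FALSE])
      }
    }
    return(M)
  }
  if (is.null(reference)) reference <- frame_coords(traj, 1L)
  reference <- as.matrix(reference)
  vapply(seq_len(F), function(i) {
    x <- frame_coords(traj, i)
    fit <- kabsch_rmsd(reference, x, fit_idx)
    fitted <- apply_fit(x, fit)
    rmsd_plain(fitted[mea_idx, , drop = FALSE],
               reference[mea_idx, , drop = FALSE])
  }, numeric(1))
}

#' Per-residue root-mean-square fluctuation
#'
#' Frames are first superposed onto the initial frame over
#' `fit_selection`, a mean structure is computed from the fitted frames,
#' and every frame is refitted onto that mean (one iteration — adequate in
#' practice and recorded in provenance). The RMSF of each measured atom is
#' the root mean squared displacement from its time-average position;
#' values are averaged within each residue.
#'
#' @param traj a [trajectory_coords()] with >= 2 frames.
#' @param fit_selection,measure_selection selections.
#' @return data.frame with columns `resid`, `rmsf` (Angstrom).
#' @export
backbone_rmsf <- function(traj, fit_selection = "backbone",
                          measure_selection = "backbone") {
  F <- n_frames(traj)
  if (F < 2L) stop("RMSF needs at least 2 frames")
  fit_idx <- resolve_selection(traj, fit_selection)
  mea_idx <- resolve_selection(traj, measure_selection)
  ref <- frame_coords(traj, 1L)
  fitted <- lapply(seq_len(F), function(i) {
    x <- frame_coords(traj, i)
    apply_fit(x, kabsch_rmsd(ref, x, fit_idx))
  })
  mean_structure <- Reduce(`+`, fitted) / F
  refitted <- lapply(seq_len(F), function(i) {
    x <- frame_coords(traj, i)
    apply_fit(x, kabsch_rmsd(mean_structure, x, fit_idx))
  })
  avg <- Reduce(`+`, refitted) / F
  sqdisp <- Reduce(`+`, lapply(refitted, function(x) rowSums((x - avg)^2))) / F
  atom_rmsf <- sqrt(sqdisp)[mea_idx]
  resid <- traj$atoms$resid[mea_idx]
  agg <- tapply(atom_rmsf, resid, mean)
  data.frame(resid = as.integer(names(agg)), rmsf = as.numeric(agg),
             row.names = NULL)
}

dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  # y-component (n1 x n2) . b2_hat gives the IUPAC sign
  m1 <- c(n1[2] * n2[3] - n1[3] * n2[2],
          n1[3] * n2[1] - n1[1] * n2[3],
          n1[1] * n2[2] - n1[2] * n2[1]) / sqrt(sum(b2^2))
  ang <- atan2(sum(m1 * b2), sum(n1 * n2)) * 180 / pi
  # atan2 yields [-180, 180]; map -180 to +180 for the (-180, 180] range
  if (ang <= -180) ang + 360 else ang
}

#' Construct a dihedral time series
#'
#' @param angles degrees in `(-180, 180]`.
#' @param definition free-text name of the quadruple (e.g. a backbone psi).
#' @param dt frame spacing (ps).
#' @return a `dihedral_series` object.
#' @export
dihedral_series <- function(angles, definition = "", dt = 1) {
  angles <- as.numeric(angles)
  if (!all(is.finite(angles))) stop("angles must be finite")
  if (any(angles <= -180 | angles > 180)) {
    stop("angles must be wrapped into (-180, 180]")
  }
  structure(list(angles = angles, definition = definition, dt = dt),
            class = "dihedral_series")
}

#' Signed backbone dihedral per frame
#'
#' IUPAC sign convention: the angle between the plane through atoms 1-2-3
#' and the plane through 2-3-4, signed by the handedness about the central
#' bond, wrapped into `(-180, 180]`. A planar cis arrangement is 0 degrees;
#' planar trans is 180 degrees.
#'
#' @param traj a [trajectory_coords()].
#' @param quadruple four atom identifiers: integer roster indices, or a
#'   list of four `"resid:name"` strings (e.g. `"88:N"`).
#' @param name label stored on the resulting series.
#' @return a [dihedral_series()].
#' @export
compute_dihedral_series <- function(traj, quadruple, name = "") {
  idx <- if (is.numeric(quadruple)) {
    as.integer(quadruple)
  } else {
    vapply(quadruple, function(q) {
      parts <- strsplit(q, ":", fixed = TRUE)[[1]]
      if (length(parts) != 2L) stop("atom spec must be 'resid:name': ", q)
      hit <- which(traj$atoms$resid == as.integer(parts[1]) &
                     traj$atoms$atom_name == parts[2])
      if (length(hit) != 1L) {
        stop("atom '", q, "' resolves to ", length(hit), " atoms")
      }
      hit
    }, integer(1))
  }
  if (length(idx) != 4L) stop("a dihedral needs exactly 4 atoms")
  if (any(idx < 1L | idx > nrow(traj$atoms))) stop("missing atom in quadruple")
  angles <- vapply(seq_len(n_frames(traj)), function(f) {
    xyz <- frame_coords(traj, f)
    dihedral_angle(xyz[idx[1], ], xyz[idx[2], ], xyz[idx[3], ], xyz[idx[4], ])
  }, numeric(1))
  dihedral_series(angles, definition = name, dt = traj$dt)
}

#' Per-frame distance between two atoms
#'
#' @param traj a [trajectory_coords()].
#' @param atom_a,atom_b atom identifiers (roster index or `"resid:name"`).
#' @return numeric vector of Euclidean distances (Angstrom).
#' @export
pair_distance_series <- function(traj, atom_a, atom_b) {
  one <- function(a) {
    if (is.numeric(a)) {
      a <- as.integer(a)
      if (a < 1L || a > nrow(traj$atoms)) stop("atom index out of range")
      return(a)
    }
    parts <- strsplit(a, ":", fixed = TRUE)[[1]]
    hit <- which(traj$atoms$resid == as.integer(parts[1]) &
                   traj$atoms$atom_name == parts[2])
    if (length(hit) != 1L) stop("atom '", a, "' not uniquely resolvable")
    hit
  }
  ia <- one(atom_a); ib <- one(atom_b)
  vapply(seq_len(n_frames(traj)), function(f) {
    xyz <- frame_coords(traj, f)
    sqrt(sum((xyz[ia, ] - xyz[ib, ])^2))
  }, numeric(1))
}
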