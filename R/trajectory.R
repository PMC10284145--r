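# Trajectory container and multi-model PDB I/O. The PDB reader is
# deliberately minimal: MODEL/ENDMDL frame delimiters and fixed-column
# ATOM/HETATM records, which is all the pipeline consumes. Author residue
# numbers are used as-is (no renumbering), so loop residue ranges from the
# literature map directly.

#' Construct a trajectory from coordinates
#'
#' @param coords numeric array `[n_frames, n_atoms, 3]` in Angstrom.
#' @param atoms data.frame with one row per atom: `atom_id`, `atom_name`,
#'   `resname`, `resid`, `chain`; the roster is identical in every frame.
#' @param dt frame spacing (ps).
#' @return a `trajectory_coords` object.
#' @export
trajectory_coords <- function(coords, atoms, dt = 1) {
  if (length(dim(coords)) != 3L || dim(coords)[3] != 3L) {
    stop("coords must be an [n_frames, n_atoms, 3] array")
  }
  if (!all(is.finite(coords))) stop("coordinates must be finite")
  need <- c("atom_id", "atom_name", "resname", "resid", "chain")
  if (!all(need %in% names(atoms))) {
    stop("atoms table needs columns: ", paste(need, collapse = ", "))
  }
  if (nrow(atoms) != dim(coords)[2]) {
    stop("atom roster (", nrow(atoms), ") does not match coords (",
         dim(coords)[2], " atoms)")
  }
  structure(list(coords = coords, atoms = atoms, dt = dt),
            class = "trajectory_coords")
}

#' @export
print.trajectory_coords <- function(x, ...) {
  cat(sprintf("<trajectory_coords> %d frames x %d atoms, dt = %g ps\n",
              dim(x$coords)[1], dim(x$coords)[2], x$dt))
  invisible(x)
}

n_frames <- function(traj) dim(traj$coords)[1]

frame_coords <- function(traj, i) {
  matrix(traj$coords[i, , ], ncol = 3L,
         dimnames = list(NULL, c("x", "y", "z")))
}

BACKBONE_NAMES <- c("N", "CA", "C", "O")

#' Resolve an atom selection
#'
#' Selections may be a logical vector or integer indices over the atom
#' roster, or a string in a small grammar: `"all"`, `"backbone"`
#' (N/CA/C/O), `"protein"`, `"resid A-B"` (inclusive author numbering),
#' `"resid N"`, `"name CA"`, and conjunctions joined with `" and "`, e.g.
#' `"resid 76-106 and backbone"`.
#'
#' @param traj a [trajectory_coords()] (or its `atoms` table).
#' @param sel selection (string, logical, or integer indices).
#' @return integer atom indices (1-based rows of the roster).
#' @export
resolve_selection <- function(traj, sel) {
  atoms <- if (inherits(traj, "trajectory_coords")) traj$atoms else traj
  n <- nrow(atoms)
  if (is.logical(sel)) {
    if (length(sel) != n) stop("logical selection length mismatch")
    return(which(sel))
  }
  if (is.numeric(sel)) {
    idx <- as.integer(sel)
    if (any(idx < 1L | idx > n)) stop("atom index out of range")
    return(idx)
  }
  stopifnot(is.character(sel), length(sel) == 1L)
  keep <- rep(TRUE, n)
  for (term in strsplit(sel, "\\s+and\\s+")[[1]]) {
    term <- trimws(term)
    keep <- keep & if (term %in% c("all", "protein")) {
      rep(TRUE, n)
    } else if (term == "backbone") {
      atoms$atom_name %in% BACKBONE_NAMES
    } else if (grepl("^resid\\s+\\d+\\s*-\\s*\\d+$", term)) {
      r <- as.integer(strsplit(sub("^resid\\s+", "", term), "\\s*-\\s*")[[1]])
      atoms$resid >= r[1] & atoms$resid <= r[2]
    } else if (grepl("^resid\\s+\\d+$", term)) {
      atoms$resid == as.integer(sub("^resid\\s+", "", term))
    } else if (grepl("^name\\s+\\S+$", term)) {
      atoms$atom_name == sub("^name\\s+", "", term)
    } else {
      stop("cannot parse selection term: '", term, "'")
    }
  }
  idx <- which(keep)
  if (length(idx) == 0L) stop("selection '", sel, "' matches no atoms")
  idx
}

#' Read a multi-model PDB file as a trajectory
#'
#' Frames are delimited by MODEL/ENDMDL records; a file without MODEL
#' records is a single-frame trajectory. Only ATOM/HETATM records are
#' consumed. All models must share one atom roster.
#'
#' @param path PDB file path.
#' @param dt frame spacing to attach (ps); PDB carries no time axis.
#' @return a [trajectory_coords()].
#' @export
read_multimodel_pdb <- function(path, dt = 1) {
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  model_starts <- which(trimws(rec) == "MODEL")
  atom_lines <- which(rec %in% c("ATOM  ", "HETATM"))
  if (length(atom_lines) == 0L) stop("no ATOM/HETATM records in ", path)

  parse_block <- function(ls) {
    data.frame(
      atom_id = as.integer(substr(ls, 7, 11)),
      atom_name = trimws(substr(ls, 13, 16)),
      resname = trimws(substr(ls, 18, 20)),
      chain = trimws(substr(ls, 22, 22)),
      resid = as.integer(substr(ls, 23, 26)),
      x = as.numeric(substr(ls, 31, 38)),
      y = as.numeric(substr(ls, 39, 46)),
      z = as.numeric(substr(ls, 47, 54)),
      stringsAsFactors = FALSE)
  }

  if (length(model_starts) == 0L) {
    blocks <- list(parse_block(lines[atom_lines]))
  } else {
    model_ends <- which(trimws(rec) == "ENDMDL")
    if (length(model_ends) != length(model_starts)) {
      stop("unbalanced MODEL/ENDMDL records in ", path)
    }
    blocks <- mapply(function(s, e) {
      idx <- atom_lines[atom_lines > s & atom_lines < e]
      parse_block(lines[idx])
    }, model_starts, model_ends, SIMPLIFY = FALSE)
  }

  na <- nrow(blocks[[1]])
  roster <- blocks[[1]][, c("atom_id", "atom_name", "resname", "resid",
                            "chain")]
  for (b in blocks) {
    if (nrow(b) != na ||
        !identical(b$atom_name, roster$atom_name) ||
        !identical(b$resid, roster$resid)) {
      stop("atom roster differs between models in ", path)
    }
  }
  coords <- array(NA_real_, dim = c(length(blocks), na, 3L))
  for (i in seq_along(blocks)) {
    coords[i, , ] <- as.matrix(blocks[[i]][, c("x", "y", "z")])
  }
  trajectory_coords(coords, roster, dt = dt)
}

#' Write a trajectory as a multi-model PDB file
#'
#' @param traj a [trajectory_coords()].
#' @param path output file path.
#' @export
write_multimodel_pdb <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory_coords"))
  out <- character(0)
  a <- traj$atoms
  for (f in seq_len(n_frames(traj))) {
    xyz <- frame_coords(traj, f)
    out <- c(out, sprintf("MODEL     %4d", f),
             sprintf("ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
                     a$atom_id, formatC(a$atom_name, width = 4),
                     a$resname, ifelse(nzchar(a$chain), a$chain, "A"),
                     a$resid, xyz[, 1], xyz[, 2], xyz[, 3]),
             "ENDMDL")
  }
  writeLines(c(out, "END"), path)
  invisible(path)
}
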