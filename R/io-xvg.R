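# XVG (GROMACS grace dialect) energy-trace reader/writer.
# Metadata lines start with '@' or '#' and may appear anywhere; data lines are
# whitespace-separated numbers with time (ps) in column 0.

# Unicode minus (U+2212) appears in published tables; accept it as a sign.
normalize_minus <- function(x) gsub("−", "-", x)

#' Read a GROMACS-style XVG energy trace
#'
#' Parses the grace dialect GROMACS writes for energy output: lines starting
#' with `@` or `#` are metadata and are skipped wherever they appear; the
#' remaining lines are whitespace-separated numeric columns with simulation
#' time in ps as column 0. The frame spacing `dt` is inferred from the first
#' two time stamps and the whole time column is checked for uniform spacing
#' (relative tolerance 1e-6), which catches accidental frame subsampling.
#'
#' @param con a file path or connection holding XVG text.
#' @param column 1-based index of the data column to read (column 0 is time).
#' @param leg simulation leg label for the resulting series.
#' @param replica_id replica index.
#' @param system_id complex identifier.
#' @param units unit of the energies in the file; GROMACS writes kJ/mol,
#'   which is the default and is converted to kcal/mol on construction.
#' @return an [energy_series()].
#' @export
read_energy_xvg <- function(con, column = 1L, leg = "complex",
                            replica_id = 0L, system_id = "unknown",
                            units = "kJ/mol") {
  lines <- if (is.character(con) && length(con) == 1L && !grepl("\n", con)) {
    readLines(con, warn = FALSE)
  } else if (inherits(con, "connection")) {
    readLines(con, warn = FALSE)
  } else {
    unlist(strsplit(paste(con, collapse = "\n"), "\n", fixed = TRUE))
  }
  is_meta <- grepl("^[@#]", trimws(lines)) | trimws(lines) == ""
  data_idx <- which(!is_meta)
  if (length(data_idx) < 1L) stop("XVG stream contains no data lines")

  times <- numeric(length(data_idx))
  vals <- numeric(length(data_idx))
  for (i in seq_along(data_idx)) {
    ln <- data_idx[i]
    tok <- strsplit(trimws(normalize_minus(lines[ln])), "[[:space:]]+")[[1]]
    if (length(tok) < column + 1L) {
      stop(sprintf("XVG line %d has %d columns; need column %d",
                   ln, length(tok), column))
    }
    num <- suppressWarnings(as.numeric(tok))
    bad <- which(is.na(num))
    if (length(bad) > 0L) {
      stop(sprintf("XVG parse error at line %d: non-numeric token '%s'",
                   ln, tok[bad[1]]))
    }
    times[i] <- num[1L]
    vals[i] <- num[column + 1L]
  }

  if (length(times) >= 2L) {
    dt <- times[2L] - times[1L]
    if (dt <= 0) stop("XVG time column is not strictly increasing")
    expect <- times[1L] + dt * (seq_along(times) - 1L)
    tol <- 1e-6 * max(abs(times), dt)
    if (any(abs(times - expect) > tol)) {
      stop("XVG dialect error: non-uniform time spacing ",
           "(relative tolerance 1e-6); was the trace subsampled?")
    }
  } else {
    dt <- 1.0  # single frame: spacing unobservable, use 1 ps
  }
  energy_series(vals, dt = dt, leg = leg, replica_id = replica_id,
                system_id = system_id, units = units)
}

#' Write an energy series as XVG text
#'
#' Inverse of [read_energy_xvg()] (values are written in the series'
#' original unit so a round trip reproduces the file).
#'
#' @param series an [energy_series()].
#' @param path output file path.
#' @export
write_energy_xvg <- function(series, path) {
  stopifnot(is_energy_series(series))
  vals <- series$values
  if (series$units_original == "kJ/mol") vals <- vals * KJ_PER_KCAL
  hdr <- c(sprintf("# bindcalor energy trace: leg=%s system=%s replica=%d",
                   series$leg, series$system_id, series$replica_id),
           sprintf("@ yaxis label \"Potential energy (%s)\"",
                   series$units_original))
  t <- series$dt * (seq_along(vals) - 1L)
  writeLines(c(hdr, sprintf("%.6f %.10g", t, vals)), path)
  invisible(path)
}
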