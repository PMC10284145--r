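# ITC benchmark tables: system_id, dH, TdS, dG in kcal/mol.

#' Construct a thermodynamic record
#'
#' One row of an experiment/computation table: binding enthalpy `dH`,
#' entropic term `TdS`, and free energy `dG`, all in kcal/mol. The identity
#' dG = dH - TdS is never assumed; see [infer_entropy_and_check()].
#'
#' @param system_id complex identifier.
#' @param dH,TdS,dG energies in kcal/mol (finite).
#' @param source `"experiment_ITC"` or `"computed"`.
#' @return a one-row data.frame of class `thermo_record`.
#' @export
thermo_record <- function(system_id, dH, TdS, dG, source = "experiment_ITC") {
  source <- match.arg(source, c("experiment_ITC", "computed"))
  vals <- c(dH = dH, TdS = TdS, dG = dG)
  if (!all(is.finite(vals))) stop("thermo_record energies must be finite")
  out <- data.frame(system_id = as.character(system_id),
                    dH = as.numeric(dH), TdS = as.numeric(TdS),
                    dG = as.numeric(dG), source = source,
                    stringsAsFactors = FALSE)
  class(out) <- c("thermo_record", class(out))
  out
}

parse_energy_cell <- function(x, row, col) {
  v <- suppressWarnings(as.numeric(normalize_minus(trimws(x))))
  if (any(is.na(v))) {
    stop(sprintf("unparseable %s value in row %d: '%s'",
                 col, row[which(is.na(v))[1]], x[which(is.na(v))[1]]))
  }
  v
}

#' Read an ITC benchmark table from CSV
#'
#' Expects a header with columns `system_id`, `dH`, `TdS`, `dG`
#' (order-insensitive; extra columns such as `source` are preserved).
#' Unicode minus signs (as printed in journal tables) are accepted.
#'
#' @param path CSV file path (RFC 4180, UTF-8).
#' @return a data.frame with one [thermo_record()]-shaped row per complex.
#' @export
read_benchmark_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", encoding = "UTF-8")
  need <- c("system_id", "dH", "TdS", "dG")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0L) {
    stop("benchmark table schema error: missing column(s) ",
         paste(missing, collapse = ", "))
  }
  n <- nrow(df)
  out <- data.frame(system_id = as.character(df$system_id),
                    dH = numeric(n), TdS = numeric(n), dG = numeric(n),
                    stringsAsFactors = FALSE)
  if (n > 0L) {
    for (col in c("dH", "TdS", "dG")) {
      out[[col]] <- parse_energy_cell(df[[col]], seq_len(n), col)
    }
  }
  out$source <- if ("source" %in% names(df) && n > 0L) df$source else
    rep("experiment_ITC", n)
  class(out) <- c("thermo_record", class(out))
  out
}

#' Write an ITC benchmark table to CSV
#'
#' Round-trip companion of [read_benchmark_table()]: all fields are
#' reproduced exactly on re-read (full-precision numerics).
#'
#' @param records data.frame of thermo records.
#' @param path output CSV file path.
#' @export
write_benchmark_table <- function(records, path) {
  stopifnot(all(c("system_id", "dH", "TdS", "dG") %in% names(records)))
  df <- records
  for (col in c("dH", "TdS", "dG")) {
    df[[col]] <- format(df[[col]], digits = 17, trim = TRUE,
                        scientific = FALSE)
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Locate a fixture table shipped with the package
#'
#' @param name file name under `extdata/`, e.g. `"table1_itc.csv"`.
#' @return absolute path.
#' @export
bindcalor_extdata <- function(name) {
  p <- system.file("extdata", name, package = "bindcalor", mustWork = FALSE)
  if (!nzchar(p)) stop("no such fixture: ", name)
  p
}
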