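# YAML run configuration and stderr logging shared by the CLI.

default_config <- function() {
  list(
    units = list(xvg = "kJ/mol", csv = "kcal/mol"),
    blocking = list(min_blocks = 8L, mode = "per_replica",
                    discard_frames = 0L),
    states = list(psi_cut = 5, phi_cut = -105, min_dwell = 5L,
                  rmsd_cut = 2.5)
  )
}

#' Read a bindcalor configuration file
#'
#' YAML with three optional sections: `units` (xvg/csv input units),
#' `blocking` (`min_blocks`, `mode`, `discard_frames`) and `states`
#' (`psi_cut`, `phi_cut` in degrees, `min_dwell` in frames, `rmsd_cut` in
#' Angstrom). Missing keys fall back to package defaults.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return nested configuration list.
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  for (sec in intersect(names(user), names(cfg))) {
    for (key in names(user[[sec]])) cfg[[sec]][[key]] <- user[[sec]][[key]]
  }
  extra <- setdiff(names(user), names(cfg))
  if (length(extra) > 0L) {
    bc_log("WARN", "ignoring unknown config section(s): ",
           paste(extra, collapse = ", "))
  }
  cfg
}

.bc_log_level <- new.env(parent = emptyenv())
.bc_log_level$threshold <- 2L  # INFO

LOG_LEVELS <- c(DEBUG = 1L, INFO = 2L, WARN = 3L, ERROR = 4L)

#' Set the logging threshold
#' @param level one of `"DEBUG"`, `"INFO"`, `"WARN"`, `"ERROR"`.
#' @export
bc_log_level <- function(level = "INFO") {
  .bc_log_level$threshold <- LOG_LEVELS[[match.arg(level, names(LOG_LEVELS))]]
  invisible(level)
}

bc_log <- function(level, ...) {
  lv <- LOG_LEVELS[[level]]
  if (lv >= .bc_log_level$threshold) {
    message(sprintf("[%s] %s", level, paste0(...)))
  }
  invisible(NULL)
}
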