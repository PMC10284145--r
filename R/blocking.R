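# Flyvbjerg-Petersen blocking: repeatedly average consecutive pairs; the SEM
# computed from blocks rises with block size until blocks decorrelate. The
# reported uncertainty is the maximum SEM across levels (conservative
# alternative to plateau detection).

#' Blocking curve for an autocorrelated series
#'
#' Level 0 is the raw series; level b+1 averages consecutive
#' non-overlapping pairs of level-b blocks, dropping an odd trailing block.
#' At each level the SEM is `sqrt(var(blocks) / n_blocks)` with the n-1
#' sample-variance denominator. Only levels retaining at least `min_blocks`
#' blocks are kept: variance estimates from a handful of blocks are too
#' noisy to let them dominate a max-SEM selection.
#'
#' @param series an [energy_series()] or numeric vector.
#' @param min_blocks smallest admissible block count per level (>= 2).
#' @return a `blocking_curve` data.frame with columns `level`, `n_blocks`,
#'   `block_mean`, `sem`.
#' @export
blocking_curve <- function(series, min_blocks = 8L) {
  x <- if (is_energy_series(series)) series$values else as.numeric(series)
  min_blocks <- as.integer(min_blocks)
  if (min_blocks < 2L) stop("min_blocks must be >= 2")
  if (length(x) < min_blocks) {
    stop(sprintf("insufficient data: %d frames < min_blocks = %d",
                 length(x), min_blocks))
  }
  n_blocks <- integer(0); block_mean <- numeric(0); sem <- numeric(0)
  b <- 0L
  while (length(x) >= min_blocks) {
    n <- length(x)
    m <- sum(x) / n
    v <- sum((x - m)^2) / (n - 1L)
    n_blocks[b + 1L] <- n
    block_mean[b + 1L] <- m
    sem[b + 1L] <- sqrt(v / n)
    half <- n %/% 2L
    x <- (x[seq(1L, 2L * half, by = 2L)] + x[seq(2L, 2L * half, by = 2L)]) / 2
    b <- b + 1L
  }
  out <- data.frame(level = seq_len(b) - 1L, n_blocks = n_blocks,
                    block_mean = block_mean, sem = sem)
  class(out) <- c("blocking_curve", class(out))
  out
}

#' Select the reported SEM from a blocking curve
#'
#' The maximum SEM over all retained levels; ties go to the lowest level
#' (the estimate backed by the most blocks).
#'
#' @param curve a [blocking_curve()].
#' @return list with `sem` and `level`.
#' @export
select_sem <- function(curve) {
  if (is.null(curve) || nrow(curve) == 0L) stop("empty blocking curve")
  i <- which.max(curve$sem)  # which.max returns the first (lowest) maximum
  list(sem = curve$sem[i], level = curve$level[i])
}

#' Estimate a leg's mean energy and uncertainty
#'
#' Combines replicas of one leg into a single `(mean, sem)`:
#' * `mode = "concat"`: replicas are concatenated in replica order and
#'   blocked as one series.
#' * `mode = "per_replica"` (default): each replica is blocked separately;
#'   the leg mean is the unweighted mean of replica means and the SEM is
#'   `max(sqrt(sum(sem_i^2)) / R, sd(replica_means) / sqrt(R))` — the
#'   within-replica quadrature or the between-replica scatter, whichever is
#'   larger. Independent repeats that disagree (e.g. trapped in different
#'   loop states) make the scatter term the honest error.
#'
#' @param replicas list of [energy_series()] sharing one leg and dt.
#' @param min_blocks passed to [blocking_curve()].
#' @param mode `"per_replica"` or `"concat"`.
#' @param discard_frames equilibration frames dropped from the start of
#'   every replica before analysis (default 0).
#' @return a `leg_estimate` list: `leg`, `mean`, `sem`, `n_replicas`,
#'   `n_frames_total`, `selection_rule`.
#' @export
estimate_leg <- function(replicas, min_blocks = 8L,
                         mode = c("per_replica", "concat"),
                         discard_frames = 0L) {
  mode <- match.arg(mode)
  if (is_energy_series(replicas)) replicas <- list(replicas)
  leg <- stopifnot_same_leg(replicas)
  if (discard_frames > 0L) {
    replicas <- lapply(replicas, function(r) {
      if (length(r$values) <= discard_frames) {
        stop("discard_frames leaves no data in replica ", r$replica_id)
      }
      r$values <- r$values[-seq_len(discard_frames)]
      r
    })
  }
  R <- length(replicas)
  n_total <- sum(vapply(replicas, function(r) length(r$values), integer(1)))

  if (mode == "concat") {
    all_vals <- unlist(lapply(replicas, `[[`, "values"))
    curve <- blocking_curve(all_vals, min_blocks)
    sel <- select_sem(curve)
    est <- list(mean = mean(all_vals), sem = sel$sem,
                rule = sprintf("concat; max-SEM at level %d", sel$level))
  } else {
    per <- lapply(replicas, function(r) {
      curve <- blocking_curve(r$values, min_blocks)
      sel <- select_sem(curve)
      c(mean = mean(r$values), sem = sel$sem)
    })
    means <- vapply(per, `[[`, numeric(1), "mean")
    sems <- vapply(per, `[[`, numeric(1), "sem")
    within <- sqrt(sum(sems^2)) / R
    between <- if (R > 1L) stats::sd(means) / sqrt(R) else 0
    est <- list(
      mean = mean(means), sem = max(within, between),
      rule = sprintf(
        "per_replica; max(quadrature %.4g, replica-scatter %.4g)",
        within, between))
  }

  structure(list(leg = leg, mean = est$mean, sem = est$sem,
                 n_replicas = R, n_frames_total = n_total,
                 selection_rule = est$rule),
            class = "leg_estimate")
}

#' @export
print.leg_estimate <- function(x, ...) {
  cat(sprintf("<leg_estimate> %s: %.4f +/- %.4f kcal/mol (%d replicas, %d frames)\n",
              x$leg, x$mean, x$sem, x$n_replicas, x$n_frames_total))
  cat("  rule:", x$selection_rule, "\n")
  invisible(x)
}

#' Construct a leg estimate directly
#'
#' For assembling estimates from externally computed means (e.g. published
#' tables) so they can flow through [combine_legs()].
#'
#' @param leg leg label.
#' @param mean,sem kcal/mol.
#' @param n_replicas,n_frames_total provenance counts.
#' @param selection_rule free-text provenance.
#' @export
leg_estimate <- function(leg, mean, sem, n_replicas = 1L,
                         n_frames_total = 0L,
                         selection_rule = "external") {
  if (!is.finite(mean)) stop("mean must be finite")
  if (!is.finite(sem) || sem < 0) stop("sem must be finite and >= 0")
  structure(list(leg = match.arg(leg, LEG_LABELS), mean = mean, sem = sem,
                 n_replicas = as.integer(n_replicas),
                 n_frames_total = as.integer(n_frames_total),
                 selection_rule = selection_rule),
            class = "leg_estimate")
}
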