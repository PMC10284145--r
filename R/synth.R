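# Synthetic data with known ground truth: stationary AR(1) energy traces,
# a hidden two-state loop process with state-dependent energy offsets and
# wrapped dihedral emissions, and noisy benchmark pairs.

#' Configuration for one synthetic simulation leg
#'
#' The generated process is first-order autoregressive,
#' `E_t = mu + rho (E_[t-1] - mu) + eps_t` with `eps_t ~ N(0, sigma^2 (1 -
#' rho^2))`, initialized from the stationary distribution `N(mu, sigma^2)`.
#' AR(1) is the minimal stationary autocorrelated stand-in for an MD
#' potential-energy trace and has a closed-form standard error of the mean,
#' `sigma * sqrt((1 + rho) / ((1 - rho) n))`, which serves as an analytic
#' oracle for the blocking analysis.
#'
#' @param mu true mean energy (kcal/mol).
#' @param sigma stationary standard deviation (kcal/mol, >= 0).
#' @param rho lag-1 autocorrelation in `[0, 1)`.
#' @param n_frames frames per replica (>= 1).
#' @param n_replicas independent replicas (default 20, the production-run
#'   replica count the pipeline is designed around).
#' @param dt frame spacing (ps).
#' @param leg leg label for the generated series.
#' @param system_id complex identifier.
#' @param seed base RNG seed; replica `r` uses `seed + r` so replicas are
#'   independent and individually reproducible.
#' @return a `leg_generator_config` list.
#' @export
leg_config <- function(mu, sigma, rho, n_frames, n_replicas = 20L,
                       dt = 10, leg = "complex", system_id = "synthetic",
                       seed = 1L) {
  if (sigma < 0) stop("sigma must be >= 0")
  if (rho < 0 || rho >= 1) stop("stationarity requires 0 <= rho < 1")
  if (n_frames < 1L) stop("n_frames must be >= 1")
  if (n_replicas < 1L) stop("n_replicas must be >= 1")
  structure(list(mu = mu, sigma = sigma, rho = rho,
                 n_frames = as.integer(n_frames),
                 n_replicas = as.integer(n_replicas), dt = dt,
                 leg = match.arg(leg, LEG_LABELS),
                 system_id = system_id, seed = as.integer(seed)),
            class = "leg_generator_config")
}

ar1_draw <- function(n, mu, sigma, rho) {
  if (sigma == 0) return(rep(mu, n))
  z0 <- stats::rnorm(1L, 0, sigma)
  if (n == 1L) return(mu + z0)
  innov <- stats::rnorm(n - 1L, 0, sigma * sqrt(1 - rho^2))
  z <- stats::filter(innov, rho, method = "recursive", init = z0)
  mu + c(z0, as.numeric(z))
}

#' Generate AR(1) energy replicas for one leg
#'
#' @param config a [leg_config()].
#' @return list of [energy_series()], one per replica (`replica_id` 0-based).
#' @export
generate_ar1_leg <- function(config) {
  stopifnot(inherits(config, "leg_generator_config"))
  lapply(seq_len(config$n_replicas) - 1L, function(r) {
    set.seed(config$seed + r)
    energy_series(ar1_draw(config$n_frames, config$mu, config$sigma,
                           config$rho),
                  dt = config$dt, leg = config$leg, replica_id = r,
                  system_id = config$system_id, units = "kcal/mol")
  })
}

#' Wrap angles into (-180, 180] degrees
#' @param x numeric vector of angles in degrees.
#' @export
wrap_angle <- function(x) {
  w <- x %% 360
  ifelse(w > 180, w - 360, w)
}

#' Configuration for the hidden two-state loop process
#'
#' A discrete two-state Markov chain over loop conformations ZA1
#' (crystal-like) and ZA2 (alternative, outward). Per-frame switching
#' probabilities `k12` (ZA1 -> ZA2) and `k21` (ZA2 -> ZA1) give geometric
#' dwell times with means `1/k12` and `1/k21` frames and stationary ZA2
#' occupancy `k12 / (k12 + k21)`. While in ZA2 the energy trace gains a
#' constant offset `delta_E`. Hinge dihedral emissions are drawn around
#' per-state modal centers (defaults: psi 50 deg in ZA1 vs -40 deg in ZA2;
#' phi -150 deg vs -60 deg) from a wrapped normal with circular standard
#' deviation `1/sqrt(kappa)` radians, i.e. `kappa` plays the role of a
#' von Mises concentration.
#'
#' @param k12,k21 per-frame switching probabilities in `[0, 1]`.
#' @param delta_E energy offset added while in ZA2 (kcal/mol).
#' @param psi_means,phi_means length-2 named vectors `c(ZA1 = ., ZA2 = .)`
#'   of emission centers in degrees, in `(-180, 180]`.
#' @param kappa emission concentration (> 0); larger is tighter.
#' @param start_state `"ZA1"` or `"ZA2"`.
#' @param seed RNG seed.
#' @return a `two_state_config` list.
#' @export
two_state_config <- function(k12, k21, delta_E = 0,
                             psi_means = c(ZA1 = 50, ZA2 = -40),
                             phi_means = c(ZA1 = -150, ZA2 = -60),
                             kappa = 50, start_state = "ZA1", seed = 1L) {
  if (any(c(k12, k21) < 0) || any(c(k12, k21) > 1)) {
    stop("switching probabilities must lie in [0, 1]")
  }
  centers <- c(psi_means, phi_means)
  if (any(centers <= -180) || any(centers > 180)) {
    stop("emission centers must lie in (-180, 180]")
  }
  if (kappa <= 0) stop("kappa must be > 0")
  structure(list(k12 = k12, k21 = k21, delta_E = delta_E,
                 psi_means = psi_means, phi_means = phi_means,
                 kappa = kappa,
                 start_state = match.arg(start_state, c("ZA1", "ZA2")),
                 seed = as.integer(seed)),
            class = "two_state_config")
}

simulate_markov_states <- function(n, k12, k21, start_state) {
  states <- integer(n)  # 1 = ZA1, 2 = ZA2
  s <- if (start_state == "ZA1") 1L else 2L
  u <- stats::runif(n)
  for (i in seq_len(n)) {
    states[i] <- s
    p_switch <- if (s == 1L) k12 else k21
    if (u[i] < p_switch) s <- 3L - s
  }
  states
}

#' Generate a frame-aligned two-state system
#'
#' Returns an energy trace (AR(1) base plus `delta_E` while in ZA2), the
#' hidden state trace, and the two hinge-dihedral emission series, all on
#' the same frame grid. The hidden labels are the ground truth that
#' [assign_states_dihedral()] should recover from the emissions.
#'
#' @param leg_cfg a [leg_config()] (its `n_frames`, `dt` and AR(1)
#'   parameters drive the energy trace; one replica is produced per call,
#'   using `leg_cfg$seed + replica_id`).
#' @param state_cfg a [two_state_config()].
#' @param replica_id replica index (offsets both seeds).
#' @return list with `energy` ([energy_series()]), `states`
#'   ([state_trace()]), `psi` and `phi` ([dihedral_series()]).
#' @export
generate_two_state_system <- function(leg_cfg, state_cfg, replica_id = 0L) {
  stopifnot(inherits(leg_cfg, "leg_generator_config"),
            inherits(state_cfg, "two_state_config"))
  n <- leg_cfg$n_frames
  set.seed(state_cfg$seed + replica_id)
  s <- simulate_markov_states(n, state_cfg$k12, state_cfg$k21,
                              state_cfg$start_state)
  sd_deg <- (180 / pi) / sqrt(state_cfg$kappa)
  psi <- wrap_angle(state_cfg$psi_means[s] + stats::rnorm(n, 0, sd_deg))
  phi <- wrap_angle(state_cfg$phi_means[s] + stats::rnorm(n, 0, sd_deg))

  set.seed(leg_cfg$seed + replica_id)
  base <- ar1_draw(n, leg_cfg$mu, leg_cfg$sigma, leg_cfg$rho)
  e <- base + ifelse(s == 2L, state_cfg$delta_E, 0)

  labels <- c("ZA1", "ZA2")[s]
  list(
    energy = energy_series(e, dt = leg_cfg$dt, leg = leg_cfg$leg,
                           replica_id = replica_id,
                           system_id = leg_cfg$system_id,
                           units = "kcal/mol"),
    states = state_trace(labels, dt = leg_cfg$dt),
    psi = dihedral_series(unname(psi), definition = "psi hinge (N-CA-C-N)",
                          dt = leg_cfg$dt),
    phi = dihedral_series(unname(phi), definition = "phi hinge (C-N-CA-C)",
                          dt = leg_cfg$dt)
  )
}

#' Generate paired experimental/predicted benchmark values
#'
#' `predicted = true + N(0, noise_sd^2)`, for exercising benchmark metrics
#' with a known noise level.
#'
#' @param true_values numeric vector of true energies (kcal/mol).
#' @param noise_sd noise standard deviation (>= 0).
#' @param seed RNG seed.
#' @return data.frame with columns `system_id`, `experimental`, `predicted`.
#' @export
generate_benchmark_pairs <- function(true_values, noise_sd, seed = 1L) {
  if (length(true_values) < 1L) stop("true_values must be non-empty")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  set.seed(seed)
  data.frame(
    system_id = sprintf("SYS%04d", seq_along(true_values)),
    experimental = as.numeric(true_values),
    predicted = true_values + stats::rnorm(length(true_values), 0, noise_sd),
    stringsAsFactors = FALSE)
}
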