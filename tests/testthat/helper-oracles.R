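# Independent oracles, written without reference to the package internals.

# Kendall tau-b by exhaustive pair enumeration with explicit branch logic.
oracle_kendall <- function(x, y) {
  n <- length(x)
  nc <- nd <- 0
  tie_x <- tie_y <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      dx <- x[i] - x[j]
      dy <- y[i] - y[j]
      if (dx == 0 && dy == 0) { tie_x <- tie_x + 1; tie_y <- tie_y + 1 }
      else if (dx == 0) tie_x <- tie_x + 1
      else if (dy == 0) tie_y <- tie_y + 1
      else if ((dx > 0 && dy > 0) || (dx < 0 && dy < 0)) nc <- nc + 1
      else nd <- nd + 1
    }
  }
  npairs <- n * (n - 1) / 2
  (nc - nd) / sqrt((npairs - tie_x) * (npairs - tie_y))
}

# Rotation matrix from Euler angles (ZYZ convention).
euler_rot <- function(a, b, g) {
  Rz <- function(t) matrix(c(cos(t), -sin(t), 0, sin(t), cos(t), 0, 0, 0, 1),
                           3, 3, byrow = TRUE)
  Ry <- function(t) matrix(c(cos(t), 0, sin(t), 0, 1, 0, -sin(t), 0, cos(t)),
                           3, 3, byrow = TRUE)
  Rz(a) %*% Ry(b) %*% Rz(g)
}

# Minimum RMSD over rigid motions by a dense rotation grid plus Nelder-Mead
# polish; translation handled exactly by centroid alignment.
oracle_min_rmsd <- function(ref, mob) {
  refc <- sweep(ref, 2, colMeans(ref))
  mobc <- sweep(mob, 2, colMeans(mob))
  score <- function(p) {
    R <- euler_rot(p[1], p[2], p[3])
    sqrt(mean(rowSums((mobc %*% t(R) - refc)^2)))
  }
  grid <- seq(0, 2 * pi, length.out = 13)[-13]
  bgrid <- seq(0, pi, length.out = 7)
  best <- NULL; best_val <- Inf
  for (a in grid) for (b in bgrid) for (g in grid) {
    v <- score(c(a, b, g))
    if (v < best_val) { best_val <- v; best <- c(a, b, g) }
  }
  opt <- stats::optim(best, score, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000))
  opt$value
}

# Dihedral from the two plane normals, sign from the triple product.
oracle_dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  cross <- function(u, v) c(u[2] * v[3] - u[3] * v[2],
                            u[3] * v[1] - u[1] * v[3],
                            u[1] * v[2] - u[2] * v[1])
  n1 <- cross(b1, b2); n2 <- cross(b2, b3)
  cosang <- sum(n1 * n2) / sqrt(sum(n1^2) * sum(n2^2))
  ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
  if (sum(cross(n1, n2) * b2) < 0) ang <- -ang
  if (ang <= -180) ang + 360 else ang
}

# Closed-form SEM of the mean of a stationary AR(1) series (large-n form).
ar1_analytic_sem <- function(sigma, rho, n) {
  sigma * sqrt((1 + rho) / ((1 - rho) * n))
}

# Tiny rigid helix-like trajectory builder for geometry tests: n_res
# residues with 4 backbone atoms each, optionally perturbed per frame.
make_toy_traj <- function(frames, dt = 10) {
  n_atoms <- nrow(frames[[1]])
  n_res <- n_atoms %/% 4L
  atoms <- data.frame(
    atom_id = seq_len(n_atoms),
    atom_name = rep(c("N", "CA", "C", "O"), n_res),
    resname = "ALA",
    resid = rep(seq_len(n_res), each = 4L),
    chain = "A", stringsAsFactors = FALSE)
  coords <- array(0, dim = c(length(frames), n_atoms, 3L))
  for (i in seq_along(frames)) coords[i, , ] <- frames[[i]]
  bindcalor::trajectory_coords(coords, atoms, dt = dt)
}

base_backbone <- function(n_res, spacing = 3.8) {
  # staggered, non-collinear pseudo-backbone
  do.call(rbind, lapply(seq_len(n_res), function(r) {
    o <- c((r - 1) * spacing, (r %% 2) * 1.5, 0)
    rbind(o + c(0, 0, 0), o + c(1.2, 0.6, 0.3), o + c(2.4, 0.1, -0.2),
          o + c(2.9, 1.2, -0.9))
  }))
}

rigid_move <- function(x, angle_deg = 30, axis = c(0, 0, 1),
                       shift = c(1, 2, 3)) {
  axis <- axis / sqrt(sum(axis^2))
  t <- angle_deg * pi / 180
  K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  R <- diag(3) + sin(t) * K + (1 - cos(t)) * K %*% K
  sweep(x %*% t(R), 2, shift, "+")
}
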