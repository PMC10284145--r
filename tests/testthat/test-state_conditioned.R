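test_that("condition_series extracts maximal single-state runs", {
  es <- energy_series(1:5, dt = 1, leg = "complex")
  tr <- state_trace(c("ZA1", "ZA1", "ZA2", "ZA2", "ZA1"))
  cs <- condition_series(es, tr, "ZA1")
  expect_equal(cs$segments, data.frame(start = c(1L, 5L), end = c(2L, 5L)))
  expect_equal(cs$values, list(c(1, 2), 5))

  empty <- condition_series(es, state_trace(rep("ZA2", 5)), "ZA1")
  expect_equal(nrow(empty$segments), 0L)

  # UNASSIGNED frames break runs and are excluded
  tr2 <- state_trace(c("ZA1", "UNASSIGNED", "ZA1", "ZA2", "ZA2"))
  cs2 <- condition_series(es, tr2, "ZA1")
  expect_equal(cs2$segments$start, c(1L, 3L))
  expect_error(condition_series(es, state_trace(c("ZA1", "ZA2")), "ZA1"),
               "frame-aligned")
})

test_that("frame conservation: ZA1 + ZA2 + UNASSIGNED partitions frames", {
  set.seed(13)
  for (k in 1:10) {
    n <- sample(20:200, 1)
    labels <- sample(c("ZA1", "ZA2", "UNASSIGNED"), n, replace = TRUE)
    es <- energy_series(rnorm(n), 1, "complex")
    tr <- state_trace(labels)
    n1 <- sum(lengths(condition_series(es, tr, "ZA1")$values))
    n2 <- sum(lengths(condition_series(es, tr, "ZA2")$values))
    expect_equal(n1 + n2, sum(labels != "UNASSIGNED"))
    expect_equal(n1, sum(labels == "ZA1"))
  }
})

test_that("state_energy_difference recovers constructed constant means", {
  vals <- c(rep(10, 40), rep(5, 40), rep(10, 20))
  tr <- state_trace(c(rep("ZA1", 40), rep("ZA2", 40), rep("ZA1", 20)))
  es <- energy_series(vals, 1, "complex")
  res <- state_energy_difference(es, tr, min_blocks = 8)
  expect_equal(res$dE, 5.0)
  expect_equal(res$sem, 0)
  expect_equal(res$ZA1$n, 60)
  expect_error(state_energy_difference(es, state_trace(rep("ZA1", 100)), 8),
               "ZA2")
})

test_that("null coverage: same-distribution states give |dE| <= 3 sem", {
  hits <- 0L
  n_run <- 40L
  for (s in seq_len(n_run)) {
    lc <- leg_config(mu = -20, sigma = 1, rho = 0.5, n_frames = 4000,
                     n_replicas = 1, seed = 2000 + s)
    sc <- two_state_config(k12 = 0.01, k21 = 0.01, delta_E = 0,
                           seed = 3000 + s)
    sys <- generate_two_state_system(lc, sc)
    res <- state_energy_difference(sys$energy, sys$states, min_blocks = 8)
    if (abs(res$dE) <= 3 * res$sem) hits <- hits + 1L
  }
  expect_gte(hits / n_run, 0.9)
})

test_that("built-in delta_E is recovered with the ZA1-minus-ZA2 sign", {
  lc <- leg_config(mu = -20, sigma = 1, rho = 0.3, n_frames = 20000,
                   n_replicas = 1, seed = 81)
  sc <- two_state_config(k12 = 0.01, k21 = 0.01, delta_E = 5, seed = 82)
  sys <- generate_two_state_system(lc, sc)
  res <- state_energy_difference(sys$energy, sys$states, min_blocks = 8)
  expect_lt(abs(res$dE - (-5)), 3 * res$sem)  # ZA2 is higher by 5
})

make_two_state_legs <- function(seed, delta_E, n_frames = 2500,
                                n_replicas = 6) {
  complex_cfg <- leg_config(mu = -95, sigma = 1.5, rho = 0.7,
                            n_frames = n_frames, n_replicas = n_replicas,
                            leg = "complex", seed = seed)
  sc <- two_state_config(k12 = 0.01, k21 = 0.01, delta_E = delta_E,
                         seed = seed + 5000)
  sys <- lapply(seq_len(n_replicas) - 1L, function(r) {
    generate_two_state_system(complex_cfg, sc, replica_id = r)
  })
  other <- mapply(function(leg, mu, off) {
    generate_ar1_leg(leg_config(mu, 1.5, 0.7, n_frames, n_replicas,
                                leg = leg, seed = seed + off))
  }, c("solvent", "receptor", "ligand"), c(-48, -121, -19), 1:3,
  SIMPLIFY = FALSE)
  list(legs = list(complex = lapply(sys, `[[`, "energy"),
                   solvent = other$solvent, receptor = other$receptor,
                   ligand = other$ligand),
       traces = lapply(sys, `[[`, "states"))
}

test_that("no-op conditioning: all-ZA1 frames make ZA1 identical to all", {
  d <- make_two_state_legs(seed = 90, delta_E = 0, n_replicas = 3)
  all_za1 <- lapply(d$traces, function(t) {
    state_trace(rep("ZA1", length(t$labels)), dt = t$dt)
  })
  a <- conditional_enthalpy(d$legs, all_za1, condition = "ZA1")
  b <- conditional_enthalpy(d$legs, all_za1, condition = "all")
  expect_equal(a$dH, b$dH, tolerance = 1e-12)
  expect_equal(a$sem, b$sem, tolerance = 1e-12)
})

test_that("conditioning is idempotent on single-state series", {
  es <- energy_series(rnorm(200, -50), 1, "complex")
  tr <- state_trace(rep("ZA2", 200))
  cs <- condition_series(es, tr, "ZA2")
  expect_equal(nrow(cs$segments), 1L)
  expect_equal(cs$values[[1]], es$values)
})

test_that("conditional enthalpy separates states by the built-in offset", {
  d <- make_two_state_legs(seed = 95, delta_E = 5)
  e1 <- conditional_enthalpy(d$legs, d$traces, condition = "ZA1")
  e2 <- conditional_enthalpy(d$legs, d$traces, condition = "ZA2")
  sem <- sqrt(e1$sem^2 + e2$sem^2)
  expect_lt(abs((e2$dH - e1$dH) - 5) , 3 * sem)
  expect_error(conditional_enthalpy(d$legs, lapply(d$traces, function(t) {
    state_trace(rep("ZA1", length(t$labels)), dt = t$dt)
  }), condition = "ZA2"), "empty in every replica")
})

test_that("pooling identity: combined equals all on the union", {
  d <- make_two_state_legs(seed = 99, delta_E = 3, n_replicas = 4)
  a <- conditional_enthalpy(d$legs, d$traces, condition = "all")
  b <- conditional_enthalpy(d$legs, d$traces, condition = "combined")
  expect_identical(a$dH, b$dH)
  expect_identical(a$sem, b$sem)
  expect_identical(b$condition, "combined")
})

test_that("entropy inference flags the one inconsistent published row", {
  tab <- read_benchmark_table(bindcalor_extdata("table1_itc.csv"))
  chk <- infer_entropy_and_check(tab)
  expect_equal(sum(chk$consistent), 9L)
  expect_identical(chk$system_id[!chk$consistent], "5DW2")
  # 5DW2 as printed: dH - dG = -2.10 but the table stores +2.10
  expect_equal(chk$TdS_computed[chk$system_id == "5DW2"], -2.10)
  expect_equal(chk$TdS_stored[chk$system_id == "5DW2"], 2.10)
  # worked single-row examples
  one <- infer_entropy_and_check(list(system_id = "3MXF", dH = -8.42,
                                      dG = -9.64, TdS = 1.22))
  expect_true(one$consistent)
  expect_equal(one$TdS_computed, 1.22)
  same <- infer_entropy_and_check(list(dH = -5, dG = -5))
  expect_equal(same$TdS_computed, 0)
})
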