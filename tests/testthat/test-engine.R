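# Langevin integration, walls, wall-force processing, reproducibility.

test_that("velocity decays as exp(-gamma t / m) at T = 0 with no forces", {
  cfg <- cfg_pairs_only(temperature = 0)
  topo <- build_topology(chain_spec("a", "G"))
  st <- md_state(topo, matrix(c(25, 25, 25), 1), c(Lx = 50, Ly = 50, s = 50),
                 cfg, velocities = matrix(c(1, 0.5, -0.3), 1))
  out <- md_run(st, 1, seed = 1, contact_update = FALSE)
  v <- out$state$r1 / cfg$dt
  expect_equal(as.numeric(v), c(1, 0.5, -0.3) * exp(-cfg$gamma * 1 / cfg$mass),
               tolerance = 1e-10)
})

test_that("a stiff harmonic dimer conserves energy without the thermostat", {
  cfg <- cfg_pairs_only(temperature = 0, gamma = 0)
  topo <- build_topology(chain_spec("a", "GG"))
  st <- md_state(topo, rbind(c(25, 25, 25), c(25.381, 25, 25)),
                 c(Lx = 50, Ly = 50, s = 50), cfg,
                 velocities = matrix(0, 2, 3))
  E0 <- energy_forces(st)$energy
  st <- md_run(st, 1e4 * cfg$dt, seed = 1, contact_update = FALSE)$state
  v <- st$r1 / cfg$dt
  E1 <- energy_forces(st)$energy + 0.5 * cfg$mass * sum(v^2)
  expect_lt(abs(E1 - E0), 1e-4)
})

test_that("free particles equilibrate to <v^2> = 3 kT / m", {
  cfg <- cfg_pairs_only()
  st <- free_beads_state(100, cfg = cfg, seed = 1)
  st <- md_run(st, 10, seed = 2, contact_update = FALSE)$state  # warm up
  acc <- numeric(180)
  for (k in seq_along(acc)) {  # samples 1 tau apart (~2 m/gamma): independent
    st <- md_run(st, 1, seed = 100 + k, contact_update = FALSE)$state
    v <- st$r1 / cfg$dt
    acc[k] <- mean(rowSums(v^2))
  }
  target <- 3 * cfg$temperature / cfg$mass
  se <- stats::sd(acc) / sqrt(length(acc))
  expect_lt(abs(mean(acc) - target), 3 * se)
})

test_that("a thermalised dimer samples the Boltzmann bond-length variance", {
  cfg <- cfg_pairs_only()
  topo <- build_topology(chain_spec("a", "GG"))
  st <- md_state(topo, rbind(c(25, 25, 25), c(25.38, 25, 25)),
                 c(Lx = 50, Ly = 50, s = 50), cfg, seed = 3)
  st <- md_run(st, 10, seed = 4, contact_update = FALSE)$state
  d2 <- numeric(300)
  for (k in seq_along(d2)) {
    st <- md_run(st, 0.5, seed = 200 + k, contact_update = FALSE)$state
    r <- sqrt(sum((st$pos[2, ] - st$pos[1, ])^2))
    d2[k] <- (r - cfg$r_b)^2
  }
  # V = k dr^2 -> <dr^2> = kT / (2k) in the harmonic approximation
  target <- cfg$temperature / (2 * cfg$k_bond)
  se <- stats::sd(d2) / sqrt(length(d2))
  expect_lt(abs(mean(d2) - target), 3 * se + 0.05 * target)
})

test_that("walls are impermeable and anchors obey the attach/detach rules", {
  cfg <- cfg_pairs_only()
  chains <- make_toy_sequences(2, 10, 0.4, 0, seed = 5)
  topo <- build_topology(chains)
  # a flat-ish box so beads visit the walls
  init <- generate_initial_conformation(topo, density = 0.05, seed = 6)
  st <- md_state(topo, init$pos, init$box, cfg, seed = 7)
  st$box[3] <- max(init$pos[, 3]) + 0.6  # bring the top wall close
  out <- md_run(st, 30, seed = 8, attraction = TRUE, snapshot_stride = 50)
  zs <- vapply(out$snapshots, function(p) range(p[, 3]), numeric(2))
  expect_gte(min(zs), 0)
  expect_lte(max(zs), st$box[3])
  # attraction creates anchors eventually
  expect_gt(length(out$state$anch$bead), 0)
})

test_that("an anchored bead at the potential minimum feels ~zero force", {
  topo <- build_topology(chain_spec("a", "G"))
  st <- md_state(topo, matrix(c(10, 10, 0.5), 1), c(Lx = 20, Ly = 20, s = 20),
                 cfg_pairs_only(), velocities = matrix(0, 1, 3))
  st$anch <- list(bead = 1L, wall = 0L, ax = 10, ay = 10, lambda = 1)
  ef <- energy_forces(st)
  expect_lt(max(abs(ef$forces)), 1e-9)
  expect_equal(ef$terms[["wall"]], -4)  # sitting in the 4-eps tail minimum
  # repulsion-only below d_min pushes the bead away from the wall
  st2 <- md_state(topo, matrix(c(10, 10, 0.3), 1),
                  c(Lx = 20, Ly = 20, s = 20), cfg_pairs_only(),
                  velocities = matrix(0, 1, 3))
  expect_gt(energy_forces(st2)$forces[1, 3], 0)
})

test_that("a bead departing beyond 2 nm detaches from its anchor", {
  topo <- build_topology(chain_spec("a", "G"))
  st <- md_state(topo, matrix(c(10, 10, 2.1), 1), c(Lx = 20, Ly = 20, s = 20),
                 cfg_pairs_only(), velocities = matrix(0, 1, 3))
  st$anch <- list(bead = 1L, wall = 0L, ax = 10, ay = 10, lambda = 1)
  st2 <- update_contact_registry(st, 0.01, attraction = TRUE)
  expect_length(st2$anch$bead, 0)
  # ... and may reattach later when it returns below d_min
  st2$pos[1, 3] <- 0.4
  st3 <- update_contact_registry(st2, 0.01, attraction = TRUE)
  expect_length(st3$anch$bead, 1)
})

test_that("trajectories are bit-reproducible per seed", {
  st <- two_chain_state(n = 5)
  a <- md_run(st, 2, seed = 9)$state
  b <- md_run(st, 2, seed = 9)$state
  c <- md_run(st, 2, seed = 10)$state
  expect_identical(a$pos, b$pos)
  expect_false(identical(a$pos, c$pos))
})

test_that("block averaging of wall forces behaves like a low-pass filter", {
  t <- seq(0.01, 10, by = 0.01)
  expect_equal(measured_wall_force(t, rep(3, 1000), window = 1)$force,
               rep(3, 10), ignore_attr = TRUE)
  alt <- rep(c(1, -1), 500)
  expect_equal(max(abs(measured_wall_force(t, alt, window = 1)$force)), 0)
  expect_error(measured_wall_force(t[1:5], rep(1, 5), window = 1), "window")
})

test_that("model forces convert to ~10.4 pN per eps/nm", {
  # independent route: 1 kcal/(mol A) = 69.479 pN, and 1 eps/nm is
  # 1.5 kcal/mol over 10 A
  expect_equal(force_to_pN(1), 1.5 * 69.479 / 10, tolerance = 1e-3)
  expect_equal(force_to_pN(1), 10.42, tolerance = 1e-3)
  expect_equal(force_to_eps_nm(force_to_nN(2.5)), 2.5)
})
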