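# Pair potentials, local frames, contact classification, and consistency of
# the compiled forces with the energy surface.

cfg <- ff_config()

test_that("excluded volume is +1 at sigma0, zero at and beyond the cutoff", {
  expect_equal(excluded_volume_energy(0.5, cfg), 0)
  expect_equal(excluded_volume_energy(cfg$sigma0, cfg), 1)  # 4 - 4 + 1
  expect_equal(excluded_volume_energy(0.6, cfg), 0)
  # continuity at r_o
  expect_lt(abs(excluded_volume_energy(0.5 - 1e-9, cfg)), 1e-6)
  # capped but finite near r = 0
  expect_true(is.finite(excluded_volume_energy(1e-4, cfg)))
})

test_that("bond potential follows V = k (r - r_b)^2", {
  expect_equal(bond_energy(0.38, cfg), 0)
  expect_equal(bond_energy(0.39, cfg), 5000 * 0.01^2)  # 0.5 eps
  # stationary at the minimum
  h <- 1e-7
  expect_lt(abs(bond_energy(0.38 + h, cfg) - bond_energy(0.38 - h, cfg)) /
              (2 * h), 1e-3)
})

test_that("contact LJ minima sit at 2^(1/6) sigma with the right depths", {
  six <- 2^(1 / 6)
  # bb: minimum 0.5 nm, doubled depth
  expect_equal(contact_energy(0.5, 0.5 / six, depth = cfg$bb_multiplier), -2)
  # disulfide: minimum 0.59 nm, depth 4
  expect_equal(contact_energy(0.59, 0.59 / six, depth = cfg$SS_depth), -4)
  # generic ss contact: depth 1 at its minimum
  expect_equal(contact_energy(six * 0.6, 0.6, depth = 1), -1)
  # the minimum really is at 2^(1/6) sigma
  rs <- seq(0.5, 1.4, by = 1e-4)
  expect_equal(rs[which.min(contact_energy(rs, 0.6))], six * 0.6,
               tolerance = 1e-3)
})

test_that("electrostatics: sign, symmetry, and the permittivity scaling", {
  expect_equal(electrostatic_energy(0.8, 0, 1, cfg), 0)
  expect_equal(electrostatic_energy(0.8, 1, -1, cfg),
               electrostatic_energy(0.8, -1, 1, cfg))
  expect_lt(electrostatic_energy(0.8, 1, -1, cfg), 0)
  # with eps_r ~ r:  V(2r)/V(r) = exp(-r/lambda_D) / 4
  r <- 0.5
  expect_equal(electrostatic_energy(2 * r, 1, 1, cfg) /
                 electrostatic_energy(r, 1, 1, cfg),
               exp(-r / cfg$debye) / 4)
})

test_that("local frames behave like a proper binormal", {
  # planar right-angle triple: h perpendicular to the bead plane (z = 0)
  fr <- local_frame(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0))
  expect_true(fr$ok)
  expect_equal(abs(fr$h), c(0, 0, 1))
  expect_equal(sum(fr$h * c(1, 0, 0)), 0)
  expect_equal(sum(fr$h * c(0, 1, 0)), 0)
  # mirror reflection (z -> -z) flips the pseudo-vector components:
  # h' = (-hx, -hy, +hz), verified numerically
  refl <- function(p) c(p[1], p[2], -p[3])
  a <- c(0, 0, 0.2); b <- c(0.38, 0.1, 0.25); c3 <- c(0.7, 0.25, 0.1)
  f1 <- local_frame(a, b, c3)
  f2 <- local_frame(refl(a), refl(b), refl(c3))
  expect_equal(f2$h[1:2], -f1$h[1:2])
  expect_equal(f2$h[3], f1$h[3])
  # collinear triple is degenerate
  expect_false(local_frame(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))$ok)
})

test_that("directional criteria classify constructed geometries", {
  # two V-shaped trimers with binormals along z, stacked along z:
  # binormals point at each other -> bb
  pa <- rbind(c(-0.38, 0, 0), c(0, 0.12, 0), c(0.38, 0, 0))
  pb <- pa; pb[, 3] <- 0.4; pb[, 2] <- -pb[, 2]  # mirrored V above
  fi <- local_frame(pa[1, ], pa[2, ], pa[3, ])
  fj <- local_frame(pb[1, ], pb[2, ], pb[3, ])
  u <- (pb[2, ] - pa[2, ]); r <- sqrt(sum(u^2)); u <- u / r
  expect_equal(classify_candidate(fi, fj, u, r, "Q", "Q", cfg), "bb")
  # sidechains facing each other: ss.  The sidechain points along -n, away
  # from the curvature centre, so a V with its vertex towards the partner
  # has its sidechain facing the partner.
  pa2 <- rbind(c(-0.38, 0, -0.12), c(0, 0, 0), c(0.38, 0, -0.12))
  pb2 <- rbind(c(-0.38, 0, 0.72), c(0, 0, 0.6), c(0.38, 0, 0.72))
  fi2 <- local_frame(pa2[1, ], pa2[2, ], pa2[3, ])
  fj2 <- local_frame(pb2[1, ], pb2[2, ], pb2[3, ])
  u2 <- (pb2[2, ] - pa2[2, ]); r2 <- sqrt(sum(u2^2)); u2 <- u2 / r2
  expect_equal(sum(fi2$side * c(0, 0, 1)), 1)   # sidechain of a points up
  expect_equal(sum(fj2$side * c(0, 0, -1)), 1)  # sidechain of b points down
  expect_equal(classify_candidate(fi2, fj2, u2, r2, "Q", "Q", cfg), "ss")
  # beyond every creation distance: none
  expect_equal(classify_candidate(fi2, fj2, u2, 0.9, "Q", "Q", cfg), "none")
})

test_that("compiled forces equal minus the energy gradient for all terms", {
  # a run long enough to populate bonds, angles, dihedrals, excluded
  # volume, dynamic contacts and wall anchors
  chains <- make_toy_sequences(2, 12, 0.4, 2, seed = 3)
  topo <- build_topology(chains)
  init <- generate_initial_conformation(topo, density = 0.05, seed = 4)
  st <- md_run(md_state(topo, init$pos, init$box, seed = 5), 10, seed = 7,
               attraction = TRUE)$state
  ef <- energy_forces(st)
  expect_gt(length(st$reg$i), 0)     # contacts present
  expect_gt(length(st$anch$bead), 0) # anchors present
  num <- numeric_forces(st)
  scale <- max(1, max(abs(num)))
  expect_lt(max(abs(num - ef$forces)) / scale, 1e-5)
})

test_that("charged pairs feel the screened Coulomb force consistently", {
  topo <- build_topology(list(chain_spec("a", "K"), chain_spec("b", "E")))
  pos <- rbind(c(10, 10, 10), c(10.9, 10, 10))
  st <- md_state(topo, pos, c(Lx = 20, Ly = 20, s = 20), cfg_pairs_only(),
                 velocities = matrix(0, 2, 3))
  ef <- energy_forces(st)
  expect_equal(ef$terms[["elec"]],
               electrostatic_energy(0.9, 1, -1, st$cfg))
  num <- numeric_forces(st, h = 1e-6)
  expect_lt(max(abs(num - ef$forces)), 1e-5)
})

test_that("energy is invariant under rigid motion and periodic shifts", {
  chains <- make_toy_sequences(2, 10, 0.4, 1, seed = 6)
  topo <- build_topology(chains)
  init <- generate_initial_conformation(topo, density = 0.02, seed = 8)
  st <- md_run(md_state(topo, init$pos, init$box, seed = 2), 5, seed = 3)$state
  e0 <- energy_forces(st)$energy
  # X/Y periodic image shift: identical energy and forces
  sh <- st; sh$pos[, 1] <- sh$pos[, 1] + sh$box[1]
  expect_equal(energy_forces(sh)$energy, e0, tolerance = 1e-12)
  expect_equal(energy_forces(sh)$forces, energy_forces(st)$forces,
               tolerance = 1e-9)
  # rigid in-plane translation (away from the walls, no anchors)
  tr <- st; tr$pos[, 1] <- tr$pos[, 1] + 1.2345; tr$pos[, 2] <-
    tr$pos[, 2] - 0.77
  expect_equal(energy_forces(tr)$energy, e0, tolerance = 1e-9)
  # rigid rotation about a vertical axis through the cloud centre
  th <- 0.83; R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0,
                            0, 0, 1), 3, 3)
  ctr <- colMeans(st$pos)
  rot <- st; rot$pos <- sweep(sweep(st$pos, 2, ctr) %*% R, 2, ctr, "+")
  expect_equal(energy_forces(rot)$energy, e0, tolerance = 1e-9)
})
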