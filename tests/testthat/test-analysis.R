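# Observables: coordination, inter-chain contacts, RMSF, shape, F_max/W_max,
# modulus fits, entanglements, cavities, oscillation ratios.

test_that("coordination number counts both contact flavours", {
  st <- two_chain_state(n = 3, gap = 0.6)
  expect_equal(coordination_number(st), 0)  # nothing formed yet
  st <- update_contact_registry(st, 12)
  ntot <- nrow(contact_table(st, active_only = TRUE))
  expect_gte(ntot, 1)
  expect_equal(coordination_number(st), 2 * ntot / 6)
  expect_equal(interchain_contacts(st), ntot)  # all contacts cross chains
  expect_lte(interchain_contacts(st), nrow(contact_table(st)))
})

test_that("a single-chain system has no inter-chain contacts", {
  topo <- build_topology(chain_spec("a", strrep("Q", 10)))
  pos <- zigzag(10, origin = c(10, 10, 10))
  st <- md_state(topo, pos, c(Lx = 30, Ly = 30, s = 30), cfg_pairs_only(),
                 velocities = matrix(0, 10, 3))
  st <- update_contact_registry(st, 12)
  expect_equal(interchain_contacts(st), 0)
})

test_that("RMSF: frozen trajectory, closed form, drift invariance", {
  frozen <- replicate(5, matrix(1:12, 4, 3), simplify = FALSE)
  expect_equal(rmsf(frozen)$mean, 0)
  expect_error(rmsf(frozen[1]), "two frames")
  # one bead alternating +-a about its mean on one axis -> RMSF = a
  a <- 0.7
  base <- matrix(c(0, 0, 0, 5, 0, 0), 2, 3, byrow = TRUE)
  frames <- lapply(1:6, function(k) {
    p <- base; p[1, 1] <- a * (-1)^k; p
  })
  r <- rmsf(frames, drift_remove = FALSE)
  expect_equal(r$per_residue[1], a)
  expect_equal(r$per_residue[2], 0)
  # rigid per-frame translation is removed when drift handling is on
  set.seed(1)
  traj <- lapply(1:8, function(k) matrix(rnorm(30), 10, 3))
  shifted <- lapply(seq_along(traj), function(k)
    sweep(traj[[k]], 2, c(k, -2 * k, 0.5 * k), "+"))
  expect_equal(rmsf(shifted, drift_remove = TRUE)$per_residue,
               rmsf(traj, drift_remove = TRUE)$per_residue)
})

test_that("distortion is 0 for a sphere, 1 for a rod, eigen-consistent", {
  shell <- make_geometry_fixture("shell", r = 2, spacing = 0.3)
  expect_lt(abs(shape_summary(shell$pos)$w), 0.02)
  rod <- cbind(seq(0, 10, by = 0.1), 0, 0)
  expect_equal(shape_summary(rod)$w, 1)
  # random cloud: radii match an independently assembled inertia tensor
  set.seed(7)
  cloud <- matrix(rnorm(90), 30, 3) %*% diag(c(2, 1, 0.5))
  ss <- shape_summary(cloud)
  pc <- sweep(cloud, 2, colMeans(cloud))
  II <- matrix(0, 3, 3)
  for (k in seq_len(nrow(pc))) {
    r2 <- sum(pc[k, ]^2)
    II <- II + (diag(3) * r2 - tcrossprod(pc[k, ]))
  }
  expect_equal(ss$radii, sort(sqrt(eigen(II / nrow(pc))$values)))
  expect_true(ss$w >= -1 && ss$w <= 1)
})

test_that("F_max takes the mean of the 5 largest separated samples", {
  # sort oracle on a simple ramp
  expect_equal(fmax(1:7)$mean, mean(sort(1:7, decreasing = TRUE)[1:5]))
  expect_equal(fmax(1:7)$mean, 5)
  fm <- fmax(rep(2.5, 10))
  expect_equal(fm$mean, 2.5)
  expect_equal(fm$sd, 0)
  # permutation invariance and scale equivariance
  set.seed(3); x <- runif(50)
  expect_equal(fmax(x)$mean, fmax(sample(x))$mean)
  expect_equal(fmax(3.7 * x)$mean, 3.7 * fmax(x)$mean)
  # min_sep keeps one spike from being counted several times
  sp <- c(rep(0, 10), 10, 9.5, 9.4, rep(0, 10), 3, 0, 2, 0, 1, 0.5)
  expect_equal(sort(fmax(sp, min_sep = 2)$indices),
               sort(c(11, 13, 24, 26, 28)))
  expect_error(fmax(1:4), "shorter")
})

test_that("cross-seed combination is inverse-variance weighted", {
  # equal uncertainties: plain average
  expect_equal(fmax_combine(c(2, 4), c(0.5, 0.5))$mean, 3)
  # tighter seed dominates
  comb <- fmax_combine(c(2, 4), c(0.1, 1))
  expect_lt(comb$mean, 2.1)
  expect_equal(comb$mean, (2 / 0.01 + 4) / (1 / 0.01 + 1))
})

test_that("the modulus fit recovers planted signals", {
  omega <- 2 * pi / 40
  S <- 100; s0 <- 12
  # noiseless: exact recovery
  d <- make_planted_rheology(0.7, 0.6, omega, noise_sd = 0)
  fit <- fit_dynamic_modulus(d$time, d$strain, d$force, S, s0, omega)
  expect_equal(fit$F0, 0.7, tolerance = 1e-9)
  expect_equal(fit$delta, 0.6, tolerance = 1e-9)
  expect_equal(fit$gamma0, 1 / s0, tolerance = 1e-9)
  # pure elastic: delta = 0, G'' = 0
  d0 <- make_planted_rheology(0.5, 0, omega)
  f0 <- fit_dynamic_modulus(d0$time, d0$strain, d0$force, S, s0, omega)
  expect_equal(f0$delta, 0, tolerance = 1e-9)
  expect_equal(f0$Gpp_MPa, 0, tolerance = 1e-9)
  # pure viscous: G' ~ 0, tan delta explodes
  d9 <- make_planted_rheology(0.5, pi / 2, omega)
  f9 <- fit_dynamic_modulus(d9$time, d9$strain, d9$force, S, s0, omega)
  expect_lt(abs(f9$Gp_MPa), 1e-9 * abs(f9$Gpp_MPa))
  expect_gt(abs(f9$tan_delta), 1e6)
  # Eq-identity: G'^2 + G''^2 = (phi0/gamma0)^2, across phases and SNR 5
  for (delta in c(0, pi / 4, pi / 2)) {
    dn <- make_planted_rheology(1, delta, omega, noise_sd = 0.2, seed = 42)
    fn <- fit_dynamic_modulus(dn$time, dn$strain, dn$force, S, s0, omega)
    expect_equal(fn$Gp_MPa^2 + fn$Gpp_MPa^2,
                 (fn$phi0_MPa / fn$gamma0)^2, tolerance = 1e-9)
    expect_equal(fn$delta, delta, tolerance = 0.1)
    expect_equal(fn$F0, 1, tolerance = 0.1)
  }
})

test_that("noisy fits are unbiased within Monte-Carlo error", {
  omega <- 2 * pi / 40
  est <- t(vapply(1:60, function(k) {
    d <- make_planted_rheology(0.7, 0.6, omega, noise_sd = 0.07, seed = k)
    fit <- fit_dynamic_modulus(d$time, d$strain, d$force, 100, 12, omega)
    c(fit$F0, fit$delta)
  }, numeric(2)))
  seF <- sd(est[, 1]) / sqrt(nrow(est))
  seD <- sd(est[, 2]) / sqrt(nrow(est))
  expect_lt(abs(mean(est[, 1]) - 0.7), 3 * seF + 1e-4)
  expect_lt(abs(mean(est[, 2]) - 0.6), 3 * seD + 1e-4)
})

test_that("entanglement counting: straight 0, hook 1, rotation invariant", {
  straight <- make_geometry_fixture("straight_pair")
  e0 <- entanglement_count(straight$pos, straight$chain_of)
  expect_equal(e0$l_k, straight$oracle$l_k)
  hook <- make_geometry_fixture("hook_pair")
  e1 <- entanglement_count(hook$pos, hook$chain_of)
  expect_equal(e1$l_k, hook$oracle$l_k)
  # rigid rotation leaves the count unchanged
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  R2 <- matrix(c(1, 0, 0, 0, cos(th), sin(th), 0, -sin(th), cos(th)), 3, 3)
  rp <- hook$pos %*% R %*% R2
  expect_equal(entanglement_count(rp, hook$chain_of)$l_k, 1)
})

test_that("a second threaded arch adds a second entanglement", {
  hook <- make_geometry_fixture("hook_pair", n = 21)
  n <- 21
  # a copy of the arch further along the straight chain
  arch2 <- hook$pos[1:n, ] + matrix(c(2.5, 0, 0), n, 3, byrow = TRUE)
  pos <- rbind(hook$pos, arch2)
  chain_of <- c(hook$chain_of, rep(3L, n))
  e <- entanglement_count(pos, chain_of)
  expect_equal(e$l_k, 2)
})

test_that("cavity classification: solid cluster, hollow shell, partition", {
  # dense solid block: no cavities
  g <- expand.grid(x = seq(1, 3, by = 0.35), y = seq(1, 3, by = 0.35),
                   z = seq(1, 3, by = 0.35))
  solid <- cavity_volumes(as.matrix(g), c(4, 4, 4), grid = 0.2)
  expect_equal(solid$n_cavities, 0)
  # hollow shell: one cavity, volume near the probe-adjusted analytic value
  shell <- make_geometry_fixture("shell", r = 1.5)
  cv <- cavity_volumes(shell$pos, shell$box, grid = 0.1)
  expect_equal(cv$n_cavities, 1)
  vtrue <- shell$oracle$volume(0.38, 0.25)
  expect_lt(abs(cv$v_max - vtrue) / vtrue, 0.15)
  expect_true(shell$oracle$check(cv))
  # the three classes tile the box exactly
  expect_equal(cv$v_occupied + cv$v_exterior + cv$v_cavities, cv$v_box,
               tolerance = 1e-9)
  # a bead wall through the void splits it in two
  mid <- shell$box[1] / 2
  wallg <- as.matrix(expand.grid(x = mid, y = seq(0.2, 4.8, by = 0.3),
                                 z = seq(0.2, 4.8, by = 0.3)))
  cv2 <- cavity_volumes(rbind(shell$pos, wallg), shell$box, grid = 0.1)
  expect_equal(cv2$n_cavities, cv$n_cavities + 1)
  # misuse guards
  expect_error(cavity_volumes(shell$pos, shell$box, grid = 0.5), "probe")
  expect_error(cavity_volumes(shell$pos, shell$box, rotations = 2),
               "rotation")
})

test_that("oscillation ratios propagate uncertainty like resampling", {
  a <- c(l_k = 2, F_max = 4, W_max = 6)
  expect_equal(oscillation_effect_ratios(a, a)$ratio, rep(1, 3))
  expect_equal(oscillation_effect_ratios(2 * a, a)$ratio, rep(2, 3))
  expect_error(oscillation_effect_ratios(a, c(1, 0, 2)), "zero")
  # propagated se vs a Monte-Carlo resampling oracle
  r <- oscillation_effect_ratios(c(x = 4), c(x = 2),
                                 se_after = 0.2, se_baseline = 0.1)
  set.seed(11)
  mc <- rnorm(2e5, 4, 0.2) / rnorm(2e5, 2, 0.1)
  expect_equal(r$se, sd(mc), tolerance = 0.05)
  expect_equal(r$ratio, 2)
})

test_that("end-to-end distances unwrap through the periodic boundary", {
  topo <- build_topology(chain_spec("a", strrep("Q", 6)))
  pos <- zigzag(6, origin = c(29.5, 10, 10))
  wrapped <- pos; wrapped[, 1] <- wrapped[, 1] %% 30
  e2e <- end_to_end(wrapped, topo$chain_of, box = c(30, 30, 30))
  expect_equal(e2e, sqrt(sum((pos[6, ] - pos[1, ])^2)))
})
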