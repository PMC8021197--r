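## Analysis suite: coordination numbers, inter-chain contacts, RMSF, chain
## shape, maximum force/work, dynamic modulus fits, primitive-path
## entanglements and grid-probe cavity volumes.

## unwrap chains through the X/Y periodic boundaries using bond continuity
unwrap_chains <- function(pos, chain_of, box) {
  out <- pos
  Lx <- box[1]; Ly <- box[2]
  for (ch in unique(chain_of)) {
    idx <- which(chain_of == ch)
    if (length(idx) < 2) next
    for (k in idx[-1]) {
      d <- pos[k, ] - pos[k - 1, ]
      d[1] <- d[1] - Lx * round(d[1] / Lx)
      d[2] <- d[2] - Ly * round(d[2] / Ly)
      out[k, ] <- out[k - 1, ] + d
    }
  }
  out
}

#' Coordination number
#'
#' Mean number of contacts per residue, counting dynamic and static
#' contacts combined (a dynamic contact counts once it is at least half
#' switched on; a static contact counts while its pair distance is within
#' the \eqn{f\sigma} range).
#'
#' @param state a `dsb_state`.
#' @return the coordination number z (each contact touches two residues).
#' @export
coordination_number <- function(state) {
  2 * nrow(contact_table(state, active_only = TRUE)) / nrow(state$pos)
}

#' Number of inter-chain contacts
#'
#' @param state a `dsb_state`.
#' @return count of active contacts whose beads belong to different chains.
#' @export
interchain_contacts <- function(state) {
  tab <- contact_table(state, active_only = TRUE)
  if (!nrow(tab)) return(0L)
  ch <- state$topology$chain_of
  sum(ch[tab$i] != ch[tab$j])
}

#' Root mean square fluctuation
#'
#' Per-residue RMS deviation from the residue's time-mean position over a
#' stack of snapshots.  Chains are unwrapped through the periodic
#' boundaries across frames, and (optionally) the per-frame centre-of-mass
#' motion is removed so that rigid drift does not register as mobility.
#'
#' @param snapshots list of n x 3 position matrices.
#' @param box optional `c(Lx, Ly, ...)` for periodic unwrapping.
#' @param drift_remove subtract per-frame centre-of-mass motion.
#' @return list with `per_residue` (vector) and `mean`.
#' @export
rmsf <- function(snapshots, box = NULL, drift_remove = TRUE) {
  if (length(snapshots) < 2) stop("need at least two frames")
  n <- nrow(snapshots[[1]])
  frames <- snapshots
  if (!is.null(box)) {
    for (k in seq_along(frames)[-1]) {
      d <- snapshots[[k]] - snapshots[[k - 1]]
      d[, 1] <- d[, 1] - box[1] * round(d[, 1] / box[1])
      d[, 2] <- d[, 2] - box[2] * round(d[, 2] / box[2])
      frames[[k]] <- frames[[k - 1]] + d
    }
  }
  if (drift_remove) {
    com0 <- colMeans(frames[[1]])
    frames <- lapply(frames, function(p)
      sweep(p, 2, colMeans(p) - com0))
  }
  acc <- matrix(0, n, 3); acc2 <- numeric(n)
  for (p in frames) acc <- acc + p
  mu <- acc / length(frames)
  for (p in frames) acc2 <- acc2 + rowSums((p - mu)^2)
  per <- sqrt(acc2 / length(frames))
  list(per_residue = per, mean = mean(per))
}

#' Shape summary of a point cloud
#'
#' Principal radii of inertia \eqn{R_1 \le R_2 \le R_3} (square roots of
#' the per-unit-mass inertia-tensor eigenvalues) and the distortion
#' parameter \eqn{w = \Delta R / \bar R} with
#' \eqn{\bar R = (R_1 + R_3)/2}, \eqn{\Delta R = R_2 - \bar R}:
#' 0 for an ideal sphere, 1 for an ideal rod.
#'
#' @param pos m x 3 positions of one chain (unwrapped).
#' @return list with `radii` (sorted) and `w`.
#' @export
shape_summary <- function(pos) {
  if (nrow(pos) < 3) stop("need at least 3 beads for a shape tensor")
  pc <- sweep(pos, 2, colMeans(pos))
  G <- crossprod(pc) / nrow(pc)
  I <- sum(diag(G)) * diag(3) - G
  R <- sort(sqrt(pmax(eigen(I, symmetric = TRUE)$values, 0)))
  rbar <- (R[1] + R[3]) / 2
  list(radii = R, w = (R[2] - rbar) / rbar)
}

#' Mean chain distortion of a configuration
#'
#' @param pos n x 3 positions.
#' @param chain_of chain id per bead.
#' @param box optional periodic extents for unwrapping.
#' @return list with per-chain `w` and their `mean`.
#' @export
chain_distortion <- function(pos, chain_of, box = NULL) {
  if (!is.null(box)) pos <- unwrap_chains(pos, chain_of, box)
  ws <- vapply(unique(chain_of), function(ch)
    shape_summary(pos[chain_of == ch, , drop = FALSE])$w, 0)
  list(w = ws, mean = mean(ws))
}

#' Per-chain end-to-end distances
#'
#' @inheritParams chain_distortion
#' @return numeric vector, one entry per chain (nm).
#' @export
end_to_end <- function(pos, chain_of, box = NULL) {
  if (!is.null(box)) pos <- unwrap_chains(pos, chain_of, box)
  vapply(unique(chain_of), function(ch) {
    idx <- which(chain_of == ch)
    sqrt(sum((pos[idx[length(idx)], ] - pos[idx[1], ])^2))
  }, 0)
}

#' Characteristic maximum force of a stretching curve
#'
#' Mean of the `k` largest samples of the smoothed force series (with a
#' minimum index separation so one spike is not counted `k` times), with
#' the standard deviation of those samples and the standard error of the
#' mean.
#'
#' @param force smoothed force series.
#' @param k number of top samples (5).
#' @param min_sep minimum index separation between selected samples; the
#'   smoothed series has one sample per averaging window, so the default 1
#'   simply forbids duplicates.
#' @return list with `mean`, `sd`, `se` and the selected `indices`.
#' @export
fmax <- function(force, k = 5, min_sep = 1) {
  if (length(force) < k) stop("series shorter than k")
  ord <- order(force, decreasing = TRUE)
  sel <- integer(0)
  for (i in ord) {
    if (all(abs(i - sel) >= min_sep)) sel <- c(sel, i)
    if (length(sel) == k) break
  }
  if (length(sel) < k) stop("cannot select ", k, " separated samples")
  v <- force[sel]
  list(mean = mean(v), sd = stats::sd(v), se = stats::sd(v) / sqrt(k),
       indices = sel)
}

#' Combine per-seed maximum forces by inverse-variance weighting
#'
#' @param means per-seed F_max means.
#' @param ses per-seed standard errors of the mean.
#' @return list with the weighted `mean` and its `se`.
#' @export
fmax_combine <- function(means, ses) {
  stopifnot(length(means) == length(ses), length(means) >= 1)
  if (all(ses == ses[1])) {  # incl. the all-zero edge case
    w <- rep(1, length(means))
  } else {
    floor_se <- min(ses[ses > 0]) / 1e6
    w <- 1 / pmax(ses, floor_se)^2
  }
  list(mean = sum(w * means) / sum(w), se = sqrt(1 / sum(w)))
}

#' Maximum work of extension
#'
#' @param work cumulative work series from [work_curve()].
#' @return the maximum.
#' @export
wmax <- function(work) max(work)

#' Fit the dynamic modulus from an oscillation stage
#'
#' Least-squares fit of the wall force and the drive on the
#' in-phase/quadrature basis at the known drive frequency, after discarding
#' the initial transient.  With stress amplitude \eqn{\phi_0 = F_0/S} and
#' strain amplitude \eqn{\gamma_0 = A/s_0}, the storage and loss moduli are
#' \deqn{G' = (\phi_0/\gamma_0)\cos\delta, \qquad
#'       G'' = (\phi_0/\gamma_0)\sin\delta,}
#' with the phase lag \eqn{\delta} folded into \eqn{[0, \pi)}.
#'
#' @param time time stamps (tau), measured from the oscillation start.
#' @param strain wall drive series: the shear offset s' (nm) for shear, or
#'   s - s0 for normal strain.
#' @param force force the moving wall applies to the sample (nN); the
#'   component along the drive direction.
#' @param S wall surface area in nm^2.
#' @param s0 reference wall separation in nm.
#' @param omega drive angular frequency in 1/tau.
#' @param discard_periods initial transient to drop (in drive periods).
#' @return an object of class `rheology_fit`: `F0` (nN), `delta` (rad),
#'   `gamma0`, `phi0_MPa`, `Gp_MPa`, `Gpp_MPa`, `tan_delta` and a
#'   `low_signal` flag.
#' @export
fit_dynamic_modulus <- function(time, strain, force, S, s0, omega,
                                discard_periods = 1) {
  period <- 2 * pi / omega
  keep <- time >= discard_periods * period
  if (sum(keep) < 8 || (max(time[keep]) - min(time[keep])) < period)
    stop("need at least one full period after the discard window")
  t <- time[keep]; y <- force[keep]; g <- strain[keep] / s0
  X <- cbind(1, cos(omega * t), sin(omega * t))
  cf <- stats::lm.fit(X, y)$coefficients
  cg <- stats::lm.fit(X, g)$coefficients
  Fhat <- complex(real = cf[2], imaginary = -cf[3])
  Ghat <- complex(real = cg[2], imaginary = -cg[3])
  if (Mod(Ghat) < 1e-12) stop("no strain signal at the drive frequency")
  Gstar <- (Fhat / S) / Ghat            # nN/nm^2 = GPa
  F0 <- Mod(Fhat)
  gamma0 <- Mod(Ghat)
  phi0 <- F0 / S
  delta <- Arg(Gstar)
  if (delta < 0) delta <- delta + pi
  Gp <- phi0 / gamma0 * cos(delta) * 1e3   # MPa
  Gpp <- phi0 / gamma0 * sin(delta) * 1e3
  res <- y - X %*% cf
  se_amp <- stats::sd(res) * sqrt(2 / length(y))
  out <- list(F0 = F0, delta = delta, gamma0 = gamma0,
              phi0_MPa = phi0 * 1e3,
              Gp_MPa = Gp, Gpp_MPa = Gpp,
              tan_delta = if (Gp != 0) Gpp / Gp else Inf,
              low_signal = F0 <= 2 * se_amp)
  class(out) <- "rheology_fit"
  out
}

#' @export
print.rheology_fit <- function(x, ...) {
  cat(sprintf(
    "G' = %.3g MPa, G'' = %.3g MPa, tan delta = %.3g (delta = %.3f rad)%s\n",
    x$Gp_MPa, x$Gpp_MPa, x$tan_delta, x$delta,
    if (x$low_signal) " [low signal]" else ""))
  invisible(x)
}

#' Dynamic modulus of a protocol run
#'
#' Convenience wrapper: extracts the oscillation-stage drive and the force
#' on the moving wall from a [run_protocol()] result and calls
#' [fit_dynamic_modulus()].
#'
#' @param run a `dsb_protocol` with mode `"shear"` or `"normal"`.
#' @param discard_periods initial transient to drop.
#' @return a `rheology_fit`.
#' @export
rheology_from_protocol <- function(run, discard_periods = 1) {
  if (run$mode == "none") stop("the run has no oscillation stage")
  osc <- run$oscillation
  S <- run$state_post_osc$box[1] * run$state_post_osc$box[2]
  if (run$mode == "shear") {
    strain <- osc$sprime
    force <- -force_to_nN(osc$fx_top, run$cfg$epsilon_kcal)
  } else {
    strain <- osc$s - run$s0
    force <- -force_to_nN(osc$fz_top, run$cfg$epsilon_kcal)
  }
  fit_dynamic_modulus(osc$t_local, strain, force, S, run$s0,
                      run$schedule$omega, discard_periods)
}

#' Ratios of observables after/without oscillation
#'
#' @param after named numeric vector of observables from the oscillated
#'   run.
#' @param baseline matching vector from the run without oscillations.
#' @param se_after,se_baseline optional standard errors for propagation.
#' @return data.frame with `quantity`, `ratio` and propagated `se`.
#' @export
oscillation_effect_ratios <- function(after, baseline, se_after = NULL,
                                      se_baseline = NULL) {
  stopifnot(length(after) == length(baseline))
  if (any(baseline == 0)) stop("zero denominator in oscillation ratio")
  r <- after / baseline
  se <- if (!is.null(se_after) && !is.null(se_baseline))
    abs(r) * sqrt((se_after / after)^2 + (se_baseline / baseline)^2)
  else rep(NA_real_, length(r))
  data.frame(quantity = names(after) %||% seq_along(after),
             ratio = unname(r), se = unname(se))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---------------------------------------------------------------------------
# primitive-path entanglement analysis ---------------------------------------

## minimum distance between segment (p0,p1) and a set of segments (q0,q1)
## vectorised clamped closest-point computation (Ericson)
.seg_seg_dist <- function(p0, p1, q0, q1) {
  d1 <- p1 - p0                       # length-3
  d2 <- q1 - q0                       # m x 3
  r <- matrix(p0, nrow(q0), 3, byrow = TRUE) - q0
  a <- sum(d1 * d1)
  e <- rowSums(d2 * d2)
  f <- rowSums(d2 * r)
  cvec <- as.vector(r %*% d1)
  b <- as.vector(d2 %*% d1)
  denom <- pmax(a * e - b * b, 1e-12)
  s <- pmin(pmax((b * f - cvec * e) / denom, 0), 1)
  t <- (b * s + f) / pmax(e, 1e-12)
  t <- pmin(pmax(t, 0), 1)
  s <- pmin(pmax((b * t - cvec) / max(a, 1e-12), 0), 1)
  cp <- matrix(p0, nrow(q0), 3, byrow = TRUE) + outer(s, d1)
  cq <- q0 + d2 * t
  sqrt(rowSums((cp - cq)^2))
}

#' Primitive-path entanglement count
#'
#' Contracts every chain towards the straight line between its (fixed)
#' ends, forbidding moves that would bring a path segment closer than
#' `d_tube` to another chain's path (moves are capped well below `d_tube`
#' so paths cannot tunnel through one another; a path can pass through
#' itself, which excludes self-entanglements by construction).  After
#' contraction, an interior vertex whose turning angle exceeds
#' `kink_angle_deg` while lying within `contact_dist` of another chain's
#' path is a kink; runs of consecutive kink vertices count once.  The
#' entanglement count l_k is the total number of such kink runs.
#'
#' @param pos n x 3 positions.
#' @param chain_of chain id per bead.
#' @param box optional periodic extents; chains are unwrapped first.
#' @param d_tube non-crossing tube diameter (nm).
#' @param step_cap maximum vertex move per sweep (nm; < d_tube/2).
#' @param max_iter sweep budget.
#' @param tol convergence threshold on the largest vertex move (nm).
#' @param kink_angle_deg turning-angle threshold.
#' @param contact_dist interchain contact distance for a kink (nm).
#' @return list with `l_k`, per-chain kink counts, `converged`,
#'   `iterations` and the contracted `paths`.
#' @export
entanglement_count <- function(pos, chain_of, box = NULL, d_tube = 0.2,
                               step_cap = 0.08, max_iter = 500, tol = 1e-3,
                               kink_angle_deg = 10, contact_dist = 0.5) {
  stopifnot(step_cap < d_tube / 2)
  if (!is.null(box)) pos <- unwrap_chains(pos, chain_of, box)
  chains <- unique(chain_of)
  if (length(chains) < 2) stop("need at least two chains")
  paths <- lapply(chains, function(ch) pos[chain_of == ch, , drop = FALSE])
  segs <- function(p) list(a = p[-nrow(p), , drop = FALSE],
                           b = p[-1, , drop = FALSE])
  converged <- FALSE; it <- 0
  while (it < max_iter) {
    it <- it + 1
    maxmove <- 0
    for (ci in seq_along(paths)) {
      p <- paths[[ci]]
      m <- nrow(p)
      if (m < 3) next
      other <- do.call(rbind, lapply(paths[-ci], function(q)
        cbind(q[-nrow(q), , drop = FALSE], q[-1, , drop = FALSE])))
      oa <- other[, 1:3, drop = FALSE]; ob <- other[, 4:6, drop = FALSE]
      for (v in 2:(m - 1)) {
        target <- (p[v - 1, ] + p[v + 1, ]) / 2
        d <- target - p[v, ]
        dn <- sqrt(sum(d^2))
        if (dn < 1e-12) next
        cand <- p[v, ] + d * min(1, step_cap / dn)
        ok <- min(.seg_seg_dist(p[v - 1, ], cand, oa, ob),
                  .seg_seg_dist(cand, p[v + 1, ], oa, ob)) >= d_tube
        if (ok) {
          maxmove <- max(maxmove, sqrt(sum((cand - p[v, ])^2)))
          p[v, ] <- cand
        }
      }
      paths[[ci]] <- p
    }
    if (maxmove < tol) { converged <- TRUE; break }
  }
  # kink counting
  costhr <- cos(kink_angle_deg * pi / 180)
  kinks <- integer(length(paths))
  for (ci in seq_along(paths)) {
    p <- paths[[ci]]
    m <- nrow(p)
    if (m < 3) next
    other <- do.call(rbind, lapply(paths[-ci], function(q)
      cbind(q[-nrow(q), , drop = FALSE], q[-1, , drop = FALSE])))
    oa <- other[, 1:3, drop = FALSE]; ob <- other[, 4:6, drop = FALSE]
    flag <- logical(m)
    for (v in 2:(m - 1)) {
      u1 <- p[v, ] - p[v - 1, ]; u2 <- p[v + 1, ] - p[v, ]
      n1 <- sqrt(sum(u1^2)); n2 <- sqrt(sum(u2^2))
      if (n1 < 1e-9 || n2 < 1e-9) next
      turning <- sum(u1 * u2) / (n1 * n2) < costhr
      if (!turning) next
      near <- min(.seg_seg_dist(p[v, ], p[v, ] + 1e-9, oa, ob)) < contact_dist
      flag[v] <- near
    }
    kinks[ci] <- sum(flag & !c(FALSE, flag[-m]))  # count runs once
  }
  list(l_k = sum(kinks), kinks = kinks, converged = converged,
       iterations = it, paths = paths)
}

# ---------------------------------------------------------------------------
# grid-probe cavity analysis --------------------------------------------------

#' Cavity volumes by grid-probe classification
#'
#' Fills the box with a cubic grid and classifies every cell: *occupied*
#' if a probe of radius `probe` centred there would overlap a bead (of
#' radius `bead_radius`), *exterior* if it is probe-accessible and
#' connected to a box face (the periodic faces or either wall), and
#' *cavity* otherwise.  Cavities are the interior connected components of
#' the probe-accessible region; the three classes tile the box exactly.
#'
#' @param pos n x 3 positions (nm), inside the box.
#' @param box `c(Lx, Ly, s)`; X/Y are treated as periodic.
#' @param grid lattice constant in nm (must not exceed `probe`).
#' @param probe probe radius in nm.
#' @param bead_radius bead hard-core radius in nm.
#' @param rotations grid rotations; only the single default orientation is
#'   supported.
#' @return list with `n_cavities`, `v_max`, `v_cavities`, `v_occupied`,
#'   `v_exterior`, `v_box` (nm^3) and the per-cavity `volumes`.
#' @export
cavity_volumes <- function(pos, box, grid = 0.1, probe = 0.38,
                           bead_radius = 0.25, rotations = 1) {
  if (rotations != 1) stop("only one grid rotation is supported")
  if (grid > probe) stop("grid cell larger than the probe radius")
  Lx <- box[1]; Ly <- box[2]; Lz <- box[3]
  nx <- max(3L, round(Lx / grid)); ny <- max(3L, round(Ly / grid))
  nz <- max(3L, round(Lz / grid))
  hx <- Lx / nx; hy <- Ly / ny; hz <- Lz / nz
  cellvol <- hx * hy * hz
  R <- probe + bead_radius
  blocked <- array(FALSE, c(nx, ny, nz))
  cx <- (seq_len(nx) - 0.5) * hx
  cy <- (seq_len(ny) - 0.5) * hy
  cz <- (seq_len(nz) - 0.5) * hz
  kx <- ceiling(R / hx); ky <- ceiling(R / hy); kz <- ceiling(R / hz)
  for (b in seq_len(nrow(pos))) {
    ix0 <- round(pos[b, 1] / hx + 0.5)
    iy0 <- round(pos[b, 2] / hy + 0.5)
    iz0 <- round(pos[b, 3] / hz + 0.5)
    ix <- (ix0 - kx):(ix0 + kx); iy <- (iy0 - ky):(iy0 + ky)
    iz <- (iz0 - kz):(iz0 + kz)
    iz <- iz[iz >= 1 & iz <= nz]
    gx <- ((ix - 1) %% nx) + 1; gy <- ((iy - 1) %% ny) + 1
    dx2 <- (((ix - 0.5) * hx - pos[b, 1]))^2
    dy2 <- (((iy - 0.5) * hy - pos[b, 2]))^2
    dz2 <- (cz[iz] - pos[b, 3])^2
    d2 <- outer(outer(dx2, dy2, "+"), dz2, "+")
    hit <- which(d2 < R^2, arr.ind = TRUE)
    if (nrow(hit))
      blocked[cbind(gx[hit[, 1]], gy[hit[, 2]], iz[hit[, 3]])] <- TRUE
  }
  free <- !blocked
  dilate <- function(m) {
    g <- m
    g[c(2:nx, 1), , ] <- g[c(2:nx, 1), , ] | m
    g[c(nx, 1:(nx - 1)), , ] <- g[c(nx, 1:(nx - 1)), , ] | m
    g[, c(2:ny, 1), ] <- g[, c(2:ny, 1), ] | m
    g[, c(ny, 1:(ny - 1)), ] <- g[, c(ny, 1:(ny - 1)), ] | m
    g[, , 2:nz] <- g[, , 2:nz] | m[, , 1:(nz - 1)]
    g[, , 1:(nz - 1)] <- g[, , 1:(nz - 1)] | m[, , 2:nz]
    g
  }
  flood <- function(seed, domain) {
    cur <- seed & domain
    repeat {
      nxt <- dilate(cur) & domain
      if (!any(nxt & !cur)) return(cur)
      cur <- nxt
    }
  }
  seed <- array(FALSE, c(nx, ny, nz))
  seed[1, , ] <- TRUE; seed[nx, , ] <- TRUE
  seed[, 1, ] <- TRUE; seed[, ny, ] <- TRUE
  seed[, , 1] <- TRUE; seed[, , nz] <- TRUE
  ext <- flood(seed, free)
  cav <- free & !ext
  volumes <- numeric(0)
  remaining <- cav
  while (any(remaining)) {
    first <- which(remaining)[1]
    s0 <- array(FALSE, c(nx, ny, nz)); s0[first] <- TRUE
    comp <- flood(s0, remaining)
    volumes <- c(volumes, sum(comp) * cellvol)
    remaining <- remaining & !comp
  }
  list(n_cavities = length(volumes),
       v_max = if (length(volumes)) max(volumes) else 0,
       v_cavities = sum(volumes),
       v_occupied = sum(blocked) * cellvol,
       v_exterior = sum(ext) * cellvol,
       v_box = nx * ny * nz * cellvol,
       volumes = sort(volumes, decreasing = TRUE))
}
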