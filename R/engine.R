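## Engine surface: simulation state construction, staged Langevin runs via
## the compiled core, wall-force post-processing and snapshot writers.

## bundle the per-bead arrays the C++ core needs
topo_for_cpp <- function(topology, cfg) {
  type <- topology$residues$type
  cls_idx <- c(generic = 0L, glycine = 1L, proline = 2L)
  list(
    chain_of = as.integer(topology$chain_of),
    type_idx = match(type, AA1) - 1L,
    class_idx = unname(cls_idx[topology$residues$class]),
    is_cys = as.integer(type == "C"),
    charge = unname(cfg$charges[type]),
    bb_cap = as.numeric(unname(cfg$bb_slots[type])),
    ss_cap = as.numeric(unname(cfg$ss_slots[type]))
  )
}

#' Create a simulation state
#'
#' Packs positions, integrator derivatives, box geometry, the (empty)
#' dynamic contact registry and wall anchors into a state object.  Static
#' Go contacts declared in the topology enter the registry as permanently
#' switched-on records.  Initial velocities are Maxwell-Boltzmann at the
#' configured temperature.
#'
#' @param topology a `dsb_topology`.
#' @param pos n x 3 position matrix (nm).
#' @param box named vector `c(Lx=, Ly=, s=)` (nm).
#' @param cfg an [ff_config()].
#' @param seed integer seed for the initial velocities.
#' @param velocities optional n x 3 matrix overriding the thermal draw.
#' @return an object of class `dsb_state`.
#' @export
md_state <- function(topology, pos, box, cfg = ff_config(), seed = 1,
                     velocities = NULL) {
  n <- topology$n
  stopifnot(nrow(pos) == n)
  if (is.null(velocities)) {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    sdv <- sqrt(cfg$temperature / cfg$mass)
    velocities <- matrix(stats::rnorm(3 * n, 0, sdv), n, 3)
  }
  zero <- matrix(0, n, 3)
  sc <- topology$static_contacts
  reg <- list(i = as.integer(sc$i), j = as.integer(sc$j),
              kind = rep(5L, nrow(sc)),
              lambda = rep(1, nrow(sc)),
              dir = rep(0L, nrow(sc)),
              sigma = sc$dist / 2^(1 / 6),
              depth = rep(1, nrow(sc)))
  st <- list(
    pos = pos, r1 = velocities * cfg$dt, r2 = zero, r3 = zero, r4 = zero,
    r5 = zero,
    box = c(unname(box[c("Lx", "Ly", "s")]), 0),
    time = 0,
    reg = reg,
    anch = list(bead = integer(0), wall = integer(0), ax = numeric(0),
                ay = numeric(0), lambda = numeric(0)),
    topology = topology, cfg = cfg
  )
  class(st) <- "dsb_state"
  st
}

#' @export
print.dsb_state <- function(x, ...) {
  cat(sprintf(
    "dsb_state: %d beads, t = %.3f tau, box %.2f x %.2f x s=%.2f nm, %d contacts, %d anchors\n",
    nrow(x$pos), x$time, x$box[1], x$box[2], x$box[3], length(x$reg$i),
    length(x$anch$bead)))
  invisible(x)
}

## default stage descriptor
.stage <- function(nsteps, seed, motion = 0L, attraction = FALSE,
                   contact_update = TRUE, freeze = FALSE,
                   record_stride = 0L, snapshot_stride = 0L,
                   m_rate = 0, m_sspeed = 0, m_xspeed = 0, m_A = 0,
                   m_omega = 0, m_s0ref = 0) {
  list(nsteps = as.integer(nsteps), motion = as.integer(motion),
       attraction = attraction, contact_update = contact_update,
       freeze = freeze, record_stride = as.integer(record_stride),
       snapshot_stride = as.integer(snapshot_stride),
       m_rate = m_rate, m_sspeed = m_sspeed, m_xspeed = m_xspeed,
       m_A = m_A, m_omega = m_omega, m_s0ref = m_s0ref,
       seed = as.numeric(seed))
}

## run one stage through the compiled core, refreshing the state object
run_stage <- function(state, stage) {
  cfg <- state$cfg
  topo <- state$topology
  tc <- topo_for_cpp(topo, cfg)
  par <- par_for_cpp(cfg, any(tc$charge != 0))
  res <- cpp_run_stage(unclass(state), tc, par, stage)
  new <- res$state
  new$topology <- topo
  new$cfg <- cfg
  class(new) <- "dsb_state"
  rec <- as.data.frame(res$records)
  list(state = new, records = rec, snapshots = res$snapshots,
       snap_times = res$snap_times)
}

#' Advance a state by plain Langevin dynamics
#'
#' Integrates the Langevin equations with the Gear 5th-order
#' predictor-corrector for `duration` tau at fixed walls.  Used directly in
#' tests and for equilibration outside the staged protocol.
#'
#' @param state a `dsb_state`.
#' @param duration simulated time in tau.
#' @param seed RNG seed for the thermal noise.
#' @param attraction whether the walls attract (anchor) nearby beads.
#' @param contact_update whether the dynamic contact machinery runs.
#' @param record_stride,snapshot_stride sampling strides in steps (0 = off).
#' @param freeze if TRUE positions are frozen and only the contact/anchor
#'   bookkeeping advances (used to study the switching dynamics).
#' @return list with the new `state`, a `records` data.frame (time, wall
#'   separation and shear offset, per-wall force components in
#'   \eqn{\epsilon}/nm, contact counts) and `snapshots`.
#' @export
md_run <- function(state, duration, seed = 1, attraction = FALSE,
                   contact_update = TRUE, record_stride = 0L,
                   snapshot_stride = 0L, freeze = FALSE) {
  nsteps <- max(1L, round(duration / state$cfg$dt))
  run_stage(state, .stage(nsteps, seed, attraction = attraction,
                          contact_update = contact_update, freeze = freeze,
                          record_stride = record_stride,
                          snapshot_stride = snapshot_stride))
}

#' Update the dynamic contact registry on a frozen configuration
#'
#' Runs only the contact/anchor bookkeeping (birth, adiabatic switching,
#' death, disulfide exclusivity) for `duration` tau with the beads pinned.
#'
#' @inheritParams md_run
#' @return the updated state.
#' @export
update_contact_registry <- function(state, duration, attraction = FALSE) {
  md_run(state, duration, seed = 0, attraction = attraction,
         freeze = TRUE)$state
}

#' Energy and forces of a configuration
#'
#' Evaluates the full potential (bonds, local stiffness, excluded volume,
#' electrostatics, contacts with their current switching weights, walls)
#' and its analytic forces.
#'
#' @param state a `dsb_state`.
#' @return list with `energy`, named `terms`, per-bead `forces`
#'   (\eqn{\epsilon}/nm) and the reaction force the beads exert on each
#'   wall (`wall_fx`, `wall_fz`; bottom wall first).
#' @export
energy_forces <- function(state) {
  tc <- topo_for_cpp(state$topology, state$cfg)
  par <- par_for_cpp(state$cfg, any(tc$charge != 0))
  cpp_energy_forces(unclass(state), tc, par)
}

#' Contact registry as a data.frame
#'
#' @param state a `dsb_state`.
#' @param active_only keep only "active" records: dynamic contacts with
#'   switching weight >= 0.5, and static contacts currently within their
#'   \eqn{f \sigma} range.
#' @return data.frame with columns i, j, kind, lambda, sigma, depth.
#' @export
contact_table <- function(state, active_only = FALSE) {
  r <- state$reg
  kinds <- c("bb", "bs", "sb", "ss", "SS", "static")
  out <- data.frame(i = r$i, j = r$j, kind = kinds[r$kind + 1],
                    lambda = r$lambda, sigma = r$sigma, depth = r$depth,
                    stringsAsFactors = FALSE)
  if (active_only && nrow(out)) {
    dx <- state$pos[r$i, 1] - state$pos[r$j, 1]
    dy <- state$pos[r$i, 2] - state$pos[r$j, 2]
    dx <- dx - state$box[1] * round(dx / state$box[1])
    dy <- dy - state$box[2] * round(dy / state$box[2])
    dz <- state$pos[r$i, 3] - state$pos[r$j, 3]
    rr <- sqrt(dx^2 + dy^2 + dz^2)
    keep <- ifelse(out$kind == "static",
                   rr < state$cfg$f_cut * out$sigma * 2^(1 / 6),
                   out$lambda >= 0.5)
    out <- out[keep, , drop = FALSE]
  }
  out
}

#' Smooth a raw wall-force series by block averaging
#'
#' The instantaneous wall force is dominated by thermal noise; it is
#' reported averaged over fixed time windows (100 ns at full scale).
#'
#' @param time time stamps (tau) of the raw samples (uniform spacing).
#' @param force raw force samples.
#' @param window averaging window in tau.
#' @return data.frame with block-centre `time` and block-mean `force`.
#' @export
measured_wall_force <- function(time, force, window = 100) {
  stopifnot(length(time) == length(force), length(time) >= 1)
  dt <- if (length(time) > 1) stats::median(diff(time)) else window
  per <- max(1L, round(window / dt))
  if (per > length(force)) stop("averaging window longer than the series")
  nb <- floor(length(force) / per)
  idx <- rep(seq_len(nb), each = per)
  keep <- seq_len(nb * per)
  data.frame(
    time = tapply(time[keep], idx, mean),
    force = tapply(force[keep], idx, mean),
    row.names = NULL)
}

#' Write a snapshot as XYZ or minimal C-alpha PDB
#'
#' @param pos n x 3 position matrix (nm).
#' @param topology the matching `dsb_topology`.
#' @param file output path.
#' @param comment XYZ comment line.
#' @export
write_xyz <- function(pos, topology, file, comment = "dsbmd snapshot") {
  con <- file(file, "w"); on.exit(close(con))
  writeLines(as.character(nrow(pos)), con)
  writeLines(comment, con)
  writeLines(sprintf("%s %.4f %.4f %.4f  # chain %d",
                     topology$residues$type, pos[, 1], pos[, 2], pos[, 3],
                     topology$chain_of), con)
  invisible(file)
}

#' @rdname write_xyz
#' @export
write_pdb_ca <- function(pos, topology, file) {
  aa3 <- c(A = "ALA", C = "CYS", D = "ASP", E = "GLU", F = "PHE", G = "GLY",
           H = "HIS", I = "ILE", K = "LYS", L = "LEU", M = "MET", N = "ASN",
           P = "PRO", Q = "GLN", R = "ARG", S = "SER", T = "THR", V = "VAL",
           W = "TRP", Y = "TYR")
  ch <- LETTERS[(topology$chain_of - 1) %% 26 + 1]
  lines <- sprintf(
    "ATOM  %5d  CA  %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    seq_len(nrow(pos)), aa3[topology$residues$type], ch,
    topology$residues$resno, pos[, 1] * 10, pos[, 2] * 10, pos[, 3] * 10)
  writeLines(c(lines, "END"), file)
  invisible(file)
}

#' Read/write the engine's time-series format
#'
#' Tab-separated with a header: time (tau), wall separation s (nm), shear
#' offset sprime (nm), per-wall force components (\eqn{\epsilon}/nm) and
#' contact counts.
#'
#' @param records data.frame as returned in `$records` by [md_run()].
#' @param file path.
#' @export
write_timeseries <- function(records, file) {
  utils::write.table(records, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' @rdname write_timeseries
#' @export
read_timeseries <- function(file) {
  utils::read.table(file, header = TRUE, sep = "\t")
}
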