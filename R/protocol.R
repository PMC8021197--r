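## Rheology protocol: dilute equilibration -> compression to melt density ->
## wall attraction -> optional oscillatory shear/normal strain -> uniaxial
## extension.  All stage durations scale with one global factor so that
## desk-scale runs exercise the identical code path.

#' Build a stage schedule
#'
#' Times are given in microseconds at full scale and multiplied by `scale`;
#' speeds are divided by `scale` so that the travelled distances (and hence
#' the geometry of each stage) are preserved.  With \eqn{\tau} = 1 ns,
#' 1 mm/s = 1e-3 nm/\eqn{\tau}.
#'
#' Defaults follow the production protocol: 125 us dilute equilibration,
#' compression at 2 mm/s to the gluten melt density 3.5 residues/nm^3,
#' 150 us equilibration, 150 us with attracting walls, five oscillation
#' cycles of period 40 us (or 70 us) and amplitude 1 nm -- or 100 us extra
#' equilibration when no oscillation is applied -- then 75 us of
#' equilibration and extension to twice the wall separation at 0.5 mm/s.
#'
#' @param scale global time-scale factor (1 = full scale; desk-scale tests
#'   use ~1e-3).
#' @param period_us oscillation period in microseconds (40 or 70 in
#'   production).
#' @param amplitude oscillation amplitude A in nm.
#' @param cycles number of oscillation cycles.
#' @param rho0 target melt density in residues/nm^3.
#' @param t_eq1_us,t_eq2_us,t_eq3_us,t_eq4_us,t_extra_none_us stage
#'   durations in microseconds (full scale).
#' @param compress_speed_mm_s,pull_speed_mm_s boundary speeds in mm/s
#'   (full scale).
#' @param pull_factor final wall separation as a multiple of s0.
#' @param force_window_ns wall-force averaging window in ns (full scale).
#' @return an object of class `stage_schedule` with all quantities in
#'   intrinsic units (tau, nm, nm/tau).
#' @examples
#' sch <- stage_schedule(scale = 1e-3)
#' sch$omega * sch$amplitude < sch$pull_speed  # max wall speed during
#'                                             # oscillation is lower
#' @export
stage_schedule <- function(scale = 1, period_us = 40, amplitude = 1,
                           cycles = 5, rho0 = 3.5,
                           t_eq1_us = 125, t_eq2_us = 150, t_eq3_us = 150,
                           t_eq4_us = 75, t_extra_none_us = 100,
                           compress_speed_mm_s = 2, pull_speed_mm_s = 0.5,
                           pull_factor = 2, force_window_ns = 100) {
  stopifnot(scale > 0, period_us > 0, amplitude > 0, cycles >= 1, rho0 > 0)
  us <- 1000 * scale                       # tau per (scaled) microsecond
  sch <- list(
    scale = scale,
    t_eq1 = t_eq1_us * us, t_eq2 = t_eq2_us * us, t_eq3 = t_eq3_us * us,
    t_eq4 = t_eq4_us * us, t_extra_none = t_extra_none_us * us,
    period = period_us * us,
    omega = 2 * pi / (period_us * us),
    frequency_kHz = oscillation_frequency_kHz(period_us),
    amplitude = amplitude, cycles = cycles,
    rho0 = rho0,
    compress_speed = speed_mm_s_to_nm_tau(compress_speed_mm_s) / scale,
    pull_speed = speed_mm_s_to_nm_tau(pull_speed_mm_s) / scale,
    pull_factor = pull_factor,
    force_window = force_window_ns * scale
  )
  class(sch) <- "stage_schedule"
  sch
}

#' Compress the box to a target density
#'
#' All box dimensions shrink simultaneously (preserving the aspect ratio)
#' with the moving boundary travelling at `speed`; bead X/Y coordinates are
#' rescaled affinely with the periodic extents while the Z walls push the
#' beads.  Stops when the density reaches the target (within rounding of a
#' single step).
#'
#' @param state a `dsb_state`.
#' @param speed boundary speed in nm/tau.
#' @param target_density residues/nm^3.
#' @param seed RNG seed for the thermal noise.
#' @param record_stride sampling stride in steps.
#' @return list with the compressed `state` and the stage `records`.
#' @export
compress_box <- function(state, speed, target_density, seed = 1,
                         record_stride = 0L) {
  n <- nrow(state$pos)
  V0 <- state$box[1] * state$box[2] * state$box[3]
  rho <- n / V0
  if (rho >= target_density * (1 - 1e-9))
    return(list(state = state, records = NULL))
  shrink <- (rho / target_density)^(1 / 3)  # final/initial linear factor
  s0 <- state$box[3]
  duration <- s0 * (1 - shrink) / speed
  nsteps <- max(1L, round(duration / state$cfg$dt))
  rate <- (1 - shrink) / (nsteps * state$cfg$dt)  # relative, per tau
  out <- run_stage(state, .stage(nsteps, seed, motion = 1L, m_rate = rate,
                                 record_stride = record_stride))
  out
}

#' Uniaxial extension with force and work curves
#'
#' Moves the top wall outward at constant speed until the separation
#' reaches `target_s`, recording the response force.  The returned curve
#' holds the wall separation, the block-averaged pulling force (the force
#' the moving wall must apply, in nN) and the accumulated work
#' \eqn{W(s) = \int F\,ds} (trapezoid rule, nN nm).
#'
#' @param state an equilibrated `dsb_state` with wall attraction on.
#' @param speed pulling speed in nm/tau.
#' @param target_s final wall separation in nm.
#' @param seed RNG seed.
#' @param window force-averaging window in tau.
#' @param snapshot_stride snapshot stride in steps (0 = none).
#' @return list with `state`, raw `records`, smoothed `curve`
#'   (data.frame s, force_nN, work) and `snapshots`.
#' @export
elongate <- function(state, speed, target_s, seed = 1, window = 100,
                     snapshot_stride = 0L) {
  stopifnot(speed > 0, target_s > state$box[3])
  duration <- (target_s - state$box[3]) / speed
  nsteps <- max(1L, round(duration / state$cfg$dt))
  rs <- max(1L, round(window / state$cfg$dt / 10))
  out <- run_stage(state, .stage(nsteps, seed, motion = 2L, m_sspeed = speed,
                                 attraction = TRUE, record_stride = rs,
                                 snapshot_stride = snapshot_stride))
  rec <- out$records
  # pulling force = force the wall applies = -(force of beads on top wall)
  sm <- measured_wall_force(rec$time, -rec$fz_top, window)
  s_at <- stats::approx(rec$time, rec$s, xout = sm$time)$y
  fnN <- force_to_nN(sm$force, state$cfg$epsilon_kcal)
  list(state = out$state, records = rec,
       curve = data.frame(s = s_at, force_nN = fnN,
                          work = work_curve(s_at, fnN)),
       snapshots = out$snapshots, snap_times = out$snap_times)
}

#' Cumulative work along a force-distance curve
#'
#' @param s distances (nm), increasing.
#' @param f forces (nN).
#' @return cumulative trapezoid integral, same length as `s` (nN nm).
#' @export
work_curve <- function(s, f) {
  stopifnot(length(s) == length(f))
  if (length(s) < 2) return(rep(0, length(s)))
  c(0, cumsum(diff(s) * (utils::head(f, -1) + utils::tail(f, -1)) / 2))
}

#' Run the full rheology protocol
#'
#' Builds the dilute self-avoiding-walk start, then executes the stages of
#' [stage_schedule()]: dilute equilibration, compression to the melt
#' density, equilibration, wall attraction, optionally five oscillation
#' cycles in the normal (Z) or shear (X) direction (the Z = 0 wall never
#' moves), a return to the rest geometry, a final equilibration -- during
#' which the post-deformation observables are sampled -- and uniaxial
#' extension to `pull_factor * s0`.
#'
#' All randomness derives from `seed`; matching seeds give trajectories
#' that are identical across modes up to the end of the third
#' equilibration, so oscillated and non-oscillated observables can be
#' compared pairwise.
#'
#' @param topology a `dsb_topology`.
#' @param schedule a [stage_schedule()].
#' @param mode `"none"`, `"normal"` (Z oscillation) or `"shear"` (X).
#' @param seed master integer seed.
#' @param cfg an [ff_config()].
#' @param density_init dilute starting density in residues/nm^3.
#' @param n_snapshots_eq4 frames sampled in the post-oscillation window
#'   (used for RMSF and structure observables).
#' @param n_snapshots_pull frames sampled during the extension.
#' @param verbose print stage progress.
#' @return an object of class `dsb_protocol`: time series with stage
#'   labels, stage log, the post-oscillation state and snapshot stack, the
#'   extension curve and the final state.
#' @export
run_protocol <- function(topology, schedule, mode = c("none", "normal",
                                                      "shear"),
                         seed = 1, cfg = ff_config(), density_init = 0.1,
                         n_snapshots_eq4 = 40, n_snapshots_pull = 50,
                         verbose = FALSE) {
  mode <- match.arg(mode)
  sch <- schedule
  dt <- cfg$dt
  rs <- max(1L, round(sch$force_window / dt / 10))
  sseed <- function(id) seed * 100 + id

  init <- generate_initial_conformation(topology, density_init, seed = seed)
  state <- md_state(topology, init$pos, init$box, cfg, seed = seed)

  ts <- list(); log <- list()
  add <- function(nm, out, t0) {
    rec <- out$records
    if (!is.null(rec) && nrow(rec)) {
      rec$stage <- nm
      ts[[length(ts) + 1L]] <<- rec
    }
    log[[length(log) + 1L]] <<- data.frame(
      stage = nm, t_start = t0, duration = out$state$time - t0)
    if (verbose) message(sprintf("stage %-8s t = %.1f tau", nm,
                                 out$state$time))
    out$state
  }

  # 1. dilute equilibration
  out <- md_run(state, sch$t_eq1, seed = sseed(1), record_stride = rs)
  state <- add("eq1", out, 0)

  # 2. compression to the melt density
  t0 <- state$time
  out <- compress_box(state, sch$compress_speed, sch$rho0, seed = sseed(2),
                      record_stride = rs)
  state <- add("compress", out, t0)
  s0 <- state$box[3]

  # 3. equilibration at melt density
  t0 <- state$time
  out <- md_run(state, sch$t_eq2, seed = sseed(3), record_stride = rs)
  state <- add("eq2", out, t0)

  # 4. walls become attractive
  t0 <- state$time
  out <- md_run(state, sch$t_eq3, seed = sseed(4), attraction = TRUE,
                record_stride = rs)
  state <- add("eq3", out, t0)

  osc <- NULL
  if (mode == "none") {
    t0 <- state$time
    out <- md_run(state, sch$t_extra_none, seed = sseed(5),
                  attraction = TRUE, record_stride = rs)
    state <- add("extra_eq", out, t0)
  } else {
    # 5. move to the displaced start position s0 - A (or s' = -A)
    t0 <- state$time
    predur <- sch$amplitude / sch$pull_speed
    npre <- max(1L, round(predur / dt))
    st <- if (mode == "normal")
      .stage(npre, sseed(5), motion = 2L, m_sspeed = -sch$pull_speed,
             attraction = TRUE, record_stride = rs)
    else
      .stage(npre, sseed(5), motion = 5L, m_xspeed = -sch$pull_speed,
             attraction = TRUE, record_stride = rs)
    out <- run_stage(state, st)
    state <- add("predisplace", out, t0)

    # 6. oscillation
    t0 <- state$time
    nosc <- max(1L, round(sch$cycles * sch$period / dt))
    st <- if (mode == "normal")
      .stage(nosc, sseed(6), motion = 3L, m_A = sch$amplitude,
             m_omega = sch$omega, m_s0ref = s0, attraction = TRUE,
             record_stride = rs)
    else
      .stage(nosc, sseed(6), motion = 4L, m_A = sch$amplitude,
             m_omega = sch$omega, attraction = TRUE, record_stride = rs)
    out <- run_stage(state, st)
    osc <- out$records
    osc$t_local <- osc$time - t0
    state <- add("oscillate", out, t0)

    # 7. return to the rest geometry
    t0 <- state$time
    st <- if (mode == "normal")
      .stage(npre, sseed(7), motion = 2L, m_sspeed = sch$pull_speed,
             attraction = TRUE, record_stride = rs)
    else
      .stage(npre, sseed(7), motion = 5L, m_xspeed = sch$pull_speed,
             attraction = TRUE, record_stride = rs)
    out <- run_stage(state, st)
    state <- add("return", out, t0)
  }

  # 8. post-deformation equilibration; observables sampled here
  t0 <- state$time
  neq4 <- max(1L, round(sch$t_eq4 / dt))
  snap_stride <- max(1L, floor(neq4 / n_snapshots_eq4))
  out <- run_stage(state, .stage(neq4, sseed(8), attraction = TRUE,
                                 record_stride = rs,
                                 snapshot_stride = snap_stride))
  snaps_eq4 <- out$snapshots
  snap_t_eq4 <- out$snap_times
  state <- add("eq4", out, t0)
  state_post <- state

  # 9. uniaxial extension
  t0 <- state$time
  npull <- max(1L, round((sch$pull_factor * s0 - state$box[3]) /
                           sch$pull_speed / dt))
  pull <- elongate(state, sch$pull_speed, sch$pull_factor * s0,
                   seed = sseed(9), window = sch$force_window,
                   snapshot_stride = max(1L, floor(npull / n_snapshots_pull)))
  state <- add("pull", pull, t0)

  res <- list(
    mode = mode, seed = seed, schedule = sch, cfg = cfg,
    topology = topology,
    s0 = s0, box0 = init$box,
    timeseries = do.call(rbind, ts),
    stage_log = do.call(rbind, log),
    oscillation = osc,
    state_post_osc = state_post,
    snapshots_post = snaps_eq4, snap_times_post = snap_t_eq4,
    pull = pull,
    state_final = state
  )
  class(res) <- "dsb_protocol"
  res
}

#' @export
print.dsb_protocol <- function(x, ...) {
  cat("dsb_protocol run, mode =", x$mode, "seed =", x$seed, "\n")
  print(x$stage_log)
  invisible(x)
}
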