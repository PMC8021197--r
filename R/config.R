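## Force-field configuration: every constant of the interaction model in one
## editable list, plus the per-residue table (sidechain contact distances,
## contact capacities, charges) shipped as a TSV under inst/extdata.

AA1 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Read the per-residue parameter table
#'
#' The table carries, for each of the 20 standard residues, the residue
#' class used by the local stiffness terms (`glycine`, `proline` or
#' `generic`), the sidechain--sidechain contact distance (the Lennard-Jones
#' minimum for an ss contact is the mean of the two residues' values, in
#' nm), the number of backbone and sidechain contact slots, and the charge
#' in elementary units.  The shipped defaults are surrogate values graded
#' by residue size; they are meant to be edited when a calibrated table is
#' available.
#'
#' @param path TSV file; defaults to the table shipped with the package.
#' @return a data.frame with one row per residue.
#' @export
residue_params <- function(path = system.file("extdata", "residue_params.tsv",
                                              package = "dsbmd")) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  stopifnot(setequal(tab$residue, AA1))
  tab[match(AA1, tab$residue), , drop = FALSE]
}

#' Force-field and integration configuration
#'
#' Returns the full parameter set of the model as a named list.  All
#' energies are in \eqn{\epsilon}, lengths in nm, times in \eqn{\tau}.
#' Key entries:
#' \describe{
#'   \item{k_bond, r_b}{harmonic backbone bond, \eqn{V = k (r - r_b)^2},
#'     k = 5000 \eqn{\epsilon}/nm\eqn{^2}, minimum at 0.38 nm.}
#'   \item{r_o, sigma0}{excluded-volume cutoff 0.5 nm and
#'     \eqn{\sigma_0 = r_o \cdot 0.5^{1/6}}.}
#'   \item{bb_min, bs_min, ss_min}{Lennard-Jones minimum distances for
#'     backbone-backbone (0.5 nm), backbone-sidechain (0.68 nm) and the
#'     per-pair sidechain-sidechain matrix.}
#'   \item{bb_multiplier}{backbone-backbone contacts are twice as deep.}
#'   \item{f_cut}{a contact switches off once \eqn{r > f \sigma_{attr}};
#'     default 1.5 (1.3 is the tighter alternative).}
#'   \item{t_switch}{adiabatic switching time, 10 \eqn{\tau}.}
#'   \item{SS_depth, r_min_SS}{disulfide bridges: depth 4 \eqn{\epsilon},
#'     minimum at 0.59 nm.}
#'   \item{temperature}{0.3 \eqn{\epsilon/k_B} (around room temperature).}
#'   \item{gamma}{damping, \eqn{2 m/\tau} (overdamped regime).}
#'   \item{dt}{integration step; 0.002 \eqn{\tau} keeps the stiff bond term
#'     well inside the stability region of the Gear integrator.}
#'   \item{align_thr}{|cosine| threshold for the directional contact
#'     criteria; set to -1 to disable direction checks.}
#' }
#'
#' @param ... overrides for any entry.
#' @param residue_table per-residue parameter data.frame, see
#'   [residue_params()].
#' @return an object of class `ff_config` (a named list).
#' @examples
#' cfg <- ff_config()
#' cfg$sigma0            # 0.5 * 0.5^(1/6)
#' cfg2 <- ff_config(f_cut = 1.3)
#' @export
ff_config <- function(..., residue_table = residue_params()) {
  rt <- residue_table
  ss_min <- outer(rt$ss_min_dist, rt$ss_min_dist, function(a, b) (a + b) / 2)
  dimnames(ss_min) <- list(AA1, AA1)
  cfg <- list(
    epsilon_kcal = 1.5,
    dt = 0.002, mass = 1, gamma = 2, temperature = 0.3,
    k_bond = 5000, r_b = 0.38,
    r_o = 0.5, sigma0 = 0.5 * 0.5^(1 / 6),
    bb_min = 0.5, bs_min = 0.68, ss_min = ss_min,
    bb_multiplier = 2, ss_depth = 1,
    f_cut = 1.5, t_switch = 10,
    SS_depth = 4, r_min_SS = 0.59,
    align_thr = 0.5,
    coulomb = 138.935 / (1.5 * 4.184),  # e^2/(4 pi eps0) in eps * nm
    perm_slope = 40, debye = 1.0, elec_cutoff = 2.0,
    cap_r = 0.1, skin = 0.3, max_disp = 0.25,
    wall_depth = 4, wall_dmin = 0.5, wall_detach = 2.0,
    # local stiffness (surrogate statistical-coil-like defaults), indexed
    # by residue class: generic, glycine, proline
    ka = c(3.0, 1.5, 4.0), th0 = c(1.92, 1.92, 1.66),
    kd1 = c(0.3, 0.1, 0.5), p1 = c(0, 0, 0),
    kd3 = c(0.2, 0.1, 0.0), p3 = c(0, 0, 0),
    charges = stats::setNames(rt$charge, rt$residue),
    bb_slots = stats::setNames(rt$bb_slots, rt$residue),
    ss_slots = stats::setNames(rt$ss_slots, rt$residue),
    class = stats::setNames(rt$class, rt$residue)
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) stop("unknown config entries: ", paste(bad, collapse = ", "))
  cfg[names(dots)] <- dots
  stopifnot(cfg$r_o > 0, cfg$r_b > 0, cfg$f_cut > 1, cfg$bb_multiplier >= 1,
            cfg$dt > 0, all(cfg$ss_min > 0))
  class(cfg) <- "ff_config"
  cfg
}

## flatten an ff_config + topology into the scalar list the C++ core reads
par_for_cpp <- function(cfg, any_charges) {
  cls_idx <- c(generic = 0, glycine = 1, proline = 2)
  list(
    dt = cfg$dt, mass = cfg$mass, gamma = cfg$gamma,
    temperature = cfg$temperature,
    k_bond = cfg$k_bond, r_b = cfg$r_b, r_o = cfg$r_o, sigma0 = cfg$sigma0,
    f_cut = cfg$f_cut, t_switch = cfg$t_switch,
    bb_multiplier = cfg$bb_multiplier, ss_depth = cfg$ss_depth,
    SS_depth = cfg$SS_depth, r_min_SS = cfg$r_min_SS,
    bb_min = cfg$bb_min, bs_min = cfg$bs_min, ss_min = cfg$ss_min,
    align_thr = cfg$align_thr,
    coulomb = cfg$coulomb, perm_slope = cfg$perm_slope, debye = cfg$debye,
    elec_cutoff = cfg$elec_cutoff, any_charges = any_charges,
    cap_r = cfg$cap_r, skin = cfg$skin, max_disp = cfg$max_disp,
    wall_depth = cfg$wall_depth, wall_dmin = cfg$wall_dmin,
    wall_detach = cfg$wall_detach,
    ka = unname(cfg$ka), th0 = unname(cfg$th0),
    kd1 = unname(cfg$kd1), p1 = unname(cfg$p1),
    kd3 = unname(cfg$kd3), p3 = unname(cfg$p3)
  )
}
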