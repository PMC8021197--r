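## Deterministic toy inputs: glutamine-rich synthetic sequences, hand-built
## geometries with known entanglement/cavity oracle values, and planted
## oscillation signals.  Everything is generated in code at call time.

#' Generate glutamine-rich toy sequences and a composition file
#'
#' Synthetic stand-ins for storage-protein sequences: each chain carries a
#' fixed fraction of glutamines (rounded to `round(q_fraction * length)`),
#' `c_count` cysteines at evenly spaced deterministic positions, and the
#' remainder drawn from small neutral residues (G/S/T/A/P).  They mimic
#' only the Q/C composition of real storage proteins, nothing else.
#'
#' @param n_chains number of chains.
#' @param length residues per chain.
#' @param q_fraction glutamine fraction in [0, 1].
#' @param c_count cysteines per chain.
#' @param seed integer seed; identical seeds give identical bytes.
#' @param dir if non-NULL, write `toy.fasta` and `toy_composition.tsv`
#'   there and return the two paths; otherwise return the chain specs.
#' @return list of [chain_spec()]s, or the two file paths.
#' @export
make_toy_sequences <- function(n_chains, length, q_fraction = 0.35,
                               c_count = 2, seed = 1, dir = NULL) {
  stopifnot(q_fraction >= 0, q_fraction <= 1)
  nq <- round(q_fraction * length)
  if (nq + c_count > length)
    stop("impossible composition: Q fraction + cysteines exceed the length")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  filler <- c("G", "S", "T", "A", "P")
  chains <- lapply(seq_len(n_chains), function(k) {
    res <- rep(NA_character_, length)
    cpos <- if (c_count > 0)
      unique(round(seq(2, length - 1, length.out = c_count)))
    else integer(0)
    if (base::length(cpos) < c_count)
      stop("chain too short for ", c_count, " cysteines")
    res[cpos] <- "C"
    open <- which(is.na(res))
    qpos <- sample(open, nq)
    res[qpos] <- "Q"
    open <- which(is.na(res))
    res[open] <- sample(filler, base::length(open), replace = TRUE)
    chain_spec(sprintf("toy%02d", k), paste(res, collapse = ""), copies = 1L)
  })
  if (is.null(dir)) return(chains)
  fa <- file.path(dir, "toy.fasta")
  co <- file.path(dir, "toy_composition.tsv")
  write_composition(chains, fa, co)
  c(fasta = fa, composition = co)
}

#' Hand-built geometry fixtures with known oracle values
#'
#' \describe{
#'   \item{`straight_pair`}{two straight parallel chains; entanglement
#'     oracle 0.}
#'   \item{`hook_pair`}{one straight chain threaded under an arch whose
#'     pinned ends lie on the far side, so the arch cannot contract past
#'     it; entanglement oracle 1.}
#'   \item{`shell`}{a hollow spherical bead shell; cavity-volume oracle
#'     \eqn{4/3\,\pi\,(r - p_{eff})^3} with \eqn{p_{eff}} the probe plus
#'     bead radius.}
#' }
#' All fixtures respect the 0.5 nm minimum bead separation within a chain's
#' non-bonded pairs.
#'
#' @param kind fixture name.
#' @param n beads per chain (chain fixtures) or a spacing control (shell).
#' @param r shell radius in nm.
#' @param spacing bead spacing on the shell surface (nm).
#' @return list with `pos`, `chain_of`, `box` and `oracle` (a named list
#'   of ground-truth values with a `check` function where applicable).
#' @export
make_geometry_fixture <- function(kind = c("straight_pair", "hook_pair",
                                           "shell"),
                                  n = 21, r = 1.5, spacing = 0.4) {
  kind <- match.arg(kind)
  if (kind == "straight_pair") {
    x <- seq(-4, 4, length.out = n)
    a <- cbind(x, 0, 0); b <- cbind(x, 1.2, 0)
    pos <- rbind(a, b) + 10
    return(list(pos = pos, chain_of = rep(1:2, each = n),
                box = c(Lx = 20, Ly = 20, s = 20),
                oracle = list(l_k = 0)))
  }
  if (kind == "hook_pair") {
    # chain B: straight line along x at y = 0, z = 0
    xb <- seq(-4, 4, length.out = n)
    b <- cbind(xb, 0, 0)
    # chain A: arch in the x = 0 plane, from (0,-3,-3) over (0,0,1) to
    # (0,3,-3); its straight chord passes below B, so contraction must
    # drape the path over B.
    t <- seq(0, 1, length.out = n)
    ya <- -3 + 6 * t
    za <- -3 + 4 * exp(-(ya / 1.1)^2) * (1 + 0)  # smooth arch peaking at z=1
    a <- cbind(0, ya, za)
    pos <- rbind(a, b) + 10
    return(list(pos = pos, chain_of = rep(1:2, each = n),
                box = c(Lx = 20, Ly = 20, s = 20),
                oracle = list(l_k = 1)))
  }
  # hollow shell: Fibonacci sphere with ~spacing between beads
  npts <- max(12L, round(4 * pi * r^2 / spacing^2))
  i <- seq_len(npts) - 0.5
  phi <- acos(1 - 2 * i / npts)
  theta <- pi * (1 + sqrt(5)) * i
  pos <- cbind(r * sin(phi) * cos(theta), r * sin(phi) * sin(theta),
               r * cos(phi))
  L <- 2 * r + 2
  pos <- pos + L / 2
  check <- function(result, probe = 0.38, bead_radius = 0.25, tol = 0.15) {
    reff <- r - probe - bead_radius
    vtrue <- 4 / 3 * pi * reff^3
    abs(result$v_max - vtrue) / vtrue <= tol && result$n_cavities == 1
  }
  list(pos = pos, chain_of = rep(1L, nrow(pos)),
       box = c(Lx = L, Ly = L, s = L),
       oracle = list(
         volume = function(probe = 0.38, bead_radius = 0.25)
           4 / 3 * pi * (r - probe - bead_radius)^3,
         n_cavities = 1, check = check))
}

#' Planted oscillation signal for modulus-fit recovery tests
#'
#' Produces a strain drive \eqn{s'(t) = -A\cos(\omega t)} and a force
#' response \eqn{F(t) = F_0 \cos(\omega t + \delta - \pi)} plus white
#' noise, i.e. a response whose phase lag relative to the drive is exactly
#' `delta`, so the fitted \eqn{(F_0, \delta)} have known ground truth.
#'
#' @param F0 force amplitude (nN).
#' @param delta phase lag in rad, within [0, pi).
#' @param omega drive angular frequency (1/tau).
#' @param noise_sd white-noise standard deviation (nN).
#' @param n_periods number of drive periods (>= 2).
#' @param dt sampling interval (tau).
#' @param A drive amplitude (nm).
#' @param seed RNG seed.
#' @return data.frame with `time`, `strain`, `force`.
#' @export
make_planted_rheology <- function(F0, delta, omega, noise_sd = 0,
                                  n_periods = 6, dt = 0.05, A = 1,
                                  seed = 1) {
  stopifnot(n_periods >= 2)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  t <- seq(0, n_periods * 2 * pi / omega, by = dt)
  strain <- -A * cos(omega * t)
  force <- F0 * cos(omega * t + delta - pi) +
    stats::rnorm(length(t), 0, noise_sd)
  data.frame(time = t, strain = strain, force = force)
}
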