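## Reference (pure-R, vectorised) implementations of the pair potentials and
## the directional contact criteria.  The compiled engine mirrors these; the
## test suite cross-checks the two against each other and against central
## differences.

#' Pair potentials of the model
#'
#' `excluded_volume_energy` is the truncated-and-shifted repulsive
#' Lennard-Jones term, zero at and beyond the cutoff `r_o` = 0.5 nm:
#' \deqn{V_r(r \le r_o) = \epsilon\,(4 (\sigma_0/r)^{12} - 4 (\sigma_0/r)^6 + 1)}
#' with \eqn{\sigma_0 = r_o\,0.5^{1/6}}.  Below `cap_r` the potential
#' continues linearly so forces stay finite.
#'
#' `bond_energy` is the harmonic backbone bond
#' \eqn{V = k (r - r_b)^2} (no 1/2 -- the elastic-constant convention is
#' configurable through `k_bond`).
#'
#' `contact_energy` is the full Lennard-Jones attraction used by every
#' contact type, \eqn{V = 4 D ((\sigma/r)^{12} - (\sigma/r)^6)}, with
#' minimum \eqn{-D} at \eqn{2^{1/6}\sigma}.
#'
#' `electrostatic_energy` is a Debye-Hueckel term with
#' distance-proportional relative permittivity
#' \eqn{\epsilon_r(r) = 40\,\mathrm{nm}^{-1}\, r}:
#' \deqn{V = \frac{C\, q_i q_j}{\epsilon_r(r)\, r} e^{-r/\lambda_D}.}
#'
#' @param r distance(s) in nm.
#' @param cfg an [ff_config()].
#' @param sigma,depth Lennard-Jones sigma (nm) and depth (\eqn{\epsilon})
#'   of a contact.
#' @param qi,qj charges in elementary units.
#' @return energy in \eqn{\epsilon}.
#' @examples
#' cfg <- ff_config()
#' excluded_volume_energy(0.5, cfg)          # 0 at the cutoff
#' excluded_volume_energy(cfg$sigma0, cfg)   # +1 at sigma0
#' contact_energy(2^(1/6) * 0.5 / 2^(1/6), 0.5 / 2^(1/6), 2)  # bb depth -2
#' @export
excluded_volume_energy <- function(r, cfg = ff_config()) {
  stopifnot(all(r > 0))
  rr <- pmax(r, cfg$cap_r)
  s6 <- (cfg$sigma0 / rr)^6
  v <- 4 * s6^2 - 4 * s6 + 1
  dv <- (-48 * s6^2 + 24 * s6) / rr
  v <- ifelse(r < cfg$cap_r, v + dv * (r - cfg$cap_r), v)
  ifelse(r >= cfg$r_o, 0, v)
}

#' @rdname excluded_volume_energy
#' @export
bond_energy <- function(r, cfg = ff_config()) {
  stopifnot(all(r > 0))
  cfg$k_bond * (r - cfg$r_b)^2
}

#' @rdname excluded_volume_energy
#' @export
contact_energy <- function(r, sigma, depth = 1) {
  stopifnot(all(r > 0), all(sigma > 0))
  s6 <- (sigma / r)^6
  4 * depth * (s6^2 - s6)
}

#' @rdname excluded_volume_energy
#' @export
electrostatic_energy <- function(r, qi, qj, cfg = ff_config()) {
  stopifnot(all(r > 0))
  v <- cfg$coulomb * qi * qj / (cfg$perm_slope * r^2) * exp(-r / cfg$debye)
  ifelse(r >= cfg$elec_cutoff, 0, v)
}

#' Local backbone frame of a bead
#'
#' From three consecutive bead positions the frame yields the binormal
#' \eqn{\hat h} (the direction a backbone hydrogen bond could take) and the
#' curvature normal \eqn{\hat n}; the sidechain points along \eqn{-\hat n}.
#' Collinear triples have no frame (`ok = FALSE`) and beads without a frame
#' cannot form directional contacts at that step.
#'
#' @param p_prev,p,p_next positions (length-3 numeric) of beads i-1, i, i+1.
#' @return list with unit vectors `h`, `n`, `side` (= -n) and flag `ok`.
#' @export
local_frame <- function(p_prev, p, p_next) {
  a <- p - p_prev; b <- p_next - p
  h <- c(a[2] * b[3] - a[3] * b[2],
         a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  hn <- sqrt(sum(h^2))
  if (hn < 1e-6 * sqrt(sum(a^2)) * sqrt(sum(b^2)))
    return(list(h = c(NA, NA, NA), n = c(NA, NA, NA),
                side = c(NA, NA, NA), ok = FALSE))
  h <- h / hn
  t <- a + b; t <- t / sqrt(sum(t^2))
  cvec <- (b - a)
  cvec <- cvec - sum(cvec * t) * t
  cn <- sqrt(sum(cvec^2))
  if (cn < 1e-9)
    return(list(h = c(NA, NA, NA), n = c(NA, NA, NA),
                side = c(NA, NA, NA), ok = FALSE))
  n <- cvec / cn
  list(h = h, n = n, side = -n, ok = TRUE)
}

#' Classify a candidate contact pair
#'
#' Applies the directional criteria: a backbone-backbone (`bb`) contact
#' needs the two binormals to point along the connecting line
#' (|cos| >= threshold on both sides), a sidechain-sidechain (`ss`) contact
#' needs both sidechain directions to face the partner (signed cosine), and
#' `bs`/`sb` mix the two.  Each kind also requires the pair distance to be
#' below that kind's Lennard-Jones minimum (its creation distance).
#' Precedence is bb, ss, bs, sb.
#'
#' @param frame_i,frame_j frames from [local_frame()].
#' @param u unit vector from bead i to bead j.
#' @param r distance in nm.
#' @param type_i,type_j one-letter residue types (for the ss distance).
#' @param cfg an [ff_config()].
#' @return one of `"bb"`, `"ss"`, `"bs"`, `"sb"`, `"none"`.
#' @export
classify_candidate <- function(frame_i, frame_j, u, r, type_i, type_j,
                               cfg = ff_config()) {
  if (!isTRUE(frame_i$ok) || !isTRUE(frame_j$ok)) return("none")
  thr <- cfg$align_thr
  bi <- abs(sum(frame_i$h * u)) >= thr
  bj <- abs(sum(frame_j$h * u)) >= thr
  ci <- sum(frame_i$side * u) >= thr
  cj <- -sum(frame_j$side * u) >= thr
  dss <- cfg$ss_min[type_i, type_j]
  if (bi && bj && r < cfg$bb_min) return("bb")
  if (ci && cj && r < dss) return("ss")
  if (bi && cj && r < cfg$bs_min) return("bs")
  if (ci && bj && r < cfg$bs_min) return("sb")
  "none"
}
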