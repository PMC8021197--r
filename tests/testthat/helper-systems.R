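# Shared builders for small test systems.  Everything is generated in code.

# a config with the local stiffness switched off (pair terms only)
cfg_pairs_only <- function(...) {
  ff_config(ka = c(0, 0, 0), kd1 = c(0, 0, 0), kd3 = c(0, 0, 0), ...)
}

# n single-bead chains (free particles) in a large box
free_beads_state <- function(n = 100, L = 60, cfg = cfg_pairs_only(),
                             seed = 1) {
  specs <- lapply(seq_len(n), function(k) chain_spec(paste0("b", k), "G"))
  topo <- build_topology(specs)
  set.seed(seed)
  pos <- cbind(runif(n, 0, L), runif(n, 0, L), runif(n, 5, L - 5))
  md_state(topo, pos, c(Lx = L, Ly = L, s = L), cfg, seed = seed + 1)
}

# a zigzag chain in the xy-plane: non-degenerate frames everywhere
zigzag <- function(n, origin = c(0, 0, 0), step = 0.38, amp = 0.12,
                   dir = c(1, 0, 0), perp = c(0, 1, 0)) {
  t(vapply(seq_len(n) - 1, function(k)
    origin + k * step * dir + (k %% 2) * amp * perp, numeric(3)))
}

# two nearby zigzag glutamine chains whose sidechain directions face each
# other (vertex towards the partner), so their odd beads can form ss
# contacts at separation `gap`
two_chain_state <- function(n = 8, gap = 0.62, cfg = cfg_pairs_only(),
                            L = 30) {
  topo <- build_topology(list(
    chain_spec("a", strrep("Q", n)), chain_spec("b", strrep("Q", n))))
  pa <- zigzag(n, origin = c(10, 10, 15), amp = 0.12)
  pb <- zigzag(n, origin = c(10, 10 + gap + 0.24, 15), amp = -0.12)
  md_state(topo, rbind(pa, pb), c(Lx = L, Ly = L, s = L), cfg,
           velocities = matrix(0, 2 * n, 3))
}

# independent O(N^2) contact-count oracle: with direction thresholds
# disabled, a pair is a contact iff |i-j| >= 3 (or inter-chain), both beads
# have a usable frame (or both are cysteines within the disulfide range)
# and r is below the largest applicable creation distance
brute_force_contacts <- function(state) {
  cfg <- state$cfg
  topo <- state$topology
  pos <- state$pos
  n <- nrow(pos)
  ch <- topo$chain_of
  type <- topo$residues$type
  frames <- lapply(seq_len(n), function(i) {
    if (i == 1 || i == n || ch[i - 1] != ch[i] || ch[i + 1] != ch[i])
      return(list(ok = FALSE))
    local_frame(pos[i - 1, ], pos[i, ], pos[i + 1, ])
  })
  cnt <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (ch[i] == ch[j] && j - i < 3) next
    r <- sqrt(sum((pos[i, ] - pos[j, ])^2))
    if (type[i] == "C" && type[j] == "C" && r < cfg$r_min_SS) {
      cnt <- cnt + 1; next
    }
    if (!isTRUE(frames[[i]]$ok) || !isTRUE(frames[[j]]$ok)) next
    dmax <- max(cfg$bb_min, cfg$bs_min, cfg$ss_min[type[i], type[j]])
    if (r < dmax) cnt <- cnt + 1
  }
  cnt
}

# numeric gradient of the total energy wrt every coordinate
numeric_forces <- function(state, h = 1e-5) {
  n <- nrow(state$pos)
  num <- matrix(0, n, 3)
  for (b in seq_len(n)) for (d in 1:3) {
    sp <- state; sp$pos[b, d] <- sp$pos[b, d] + h
    sm <- state; sm$pos[b, d] <- sm$pos[b, d] - h
    num[b, d] <- -(energy_forces(sp)$energy - energy_forces(sm)$energy) /
      (2 * h)
  }
  num
}

# cached tiny protocol runs shared between test blocks
.tiny_cache <- new.env(parent = emptyenv())
tiny_protocol <- function(mode, seed = 3) {
  key <- paste(mode, seed)
  if (!is.null(.tiny_cache[[key]])) return(.tiny_cache[[key]])
  chains <- make_toy_sequences(2, 25, 0.35, 1, seed = 7)
  topo <- build_topology(chains)
  # 1e-4 of the production durations; boundary speeds kept at the intrinsic
  # values of a 1e-3 run so the compression stays gentle
  sch <- stage_schedule(scale = 1e-4, compress_speed_mm_s = 0.2,
                        pull_speed_mm_s = 0.05)
  run <- run_protocol(topo, sch, mode = mode, seed = seed,
                      n_snapshots_eq4 = 10, n_snapshots_pull = 10)
  .tiny_cache[[key]] <- run
  run
}
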