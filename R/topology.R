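## System construction: sequences + composition -> bead topology, initial
## self-avoiding-walk conformations, static contact maps for structured
## domains.

#' Specify one protein species of the simulated system
#'
#' @param name species name (must match the FASTA record name).
#' @param sequence one-letter amino-acid string (20 standard residues).
#' @param copies number of chains of this species in the box.
#' @param structured_domains optional list of `c(start, end)` residue
#'   intervals (1-based, within the sequence) that carry a static Go-type
#'   contact map; intervals must not overlap.
#' @return an object of class `chain_spec`.
#' @examples
#' chain_spec("toy", "GQQQGQQCGQ", copies = 2)
#' @export
chain_spec <- function(name, sequence, copies = 1L, structured_domains = list()) {
  sequence <- toupper(sequence)
  if (nchar(sequence) < 1) stop("empty sequence for ", name)
  res <- strsplit(sequence, "")[[1]]
  bad <- setdiff(unique(res), AA1)
  if (length(bad))
    stop("illegal residue letter(s) in ", name, ": ", paste(bad, collapse = ""))
  if (copies < 1) stop("copies must be >= 1")
  n <- length(res)
  if (length(structured_domains)) {
    dom <- do.call(rbind, lapply(structured_domains, function(d) {
      stopifnot(length(d) == 2, d[1] >= 1, d[2] <= n, d[1] < d[2])
      as.integer(d)
    }))
    o <- order(dom[, 1])
    dom <- dom[o, , drop = FALSE]
    if (nrow(dom) > 1 && any(dom[-1, 1] <= dom[-nrow(dom), 2]))
      stop("structured domains overlap in ", name)
  } else dom <- matrix(integer(0), ncol = 2)
  structure(list(name = name, sequence = sequence, copies = as.integer(copies),
                 domains = dom),
            class = "chain_spec")
}

#' Load a system composition from FASTA + composition table
#'
#' The composition file is a two-column TSV (`name<TAB>copies`, no header
#' required; a header line `name\tcopies` is tolerated).  Every name must
#' have a FASTA record.  Chains are returned in composition-file order.
#'
#' @param fasta_path FASTA file of the protein sequences.
#' @param composition_path TSV with chain counts per sequence.
#' @return a list of [chain_spec()] objects.
#' @export
load_composition <- function(fasta_path, composition_path) {
  seqs <- Biostrings::readAAStringSet(fasta_path)
  nms <- sub("\\s.*$", "", names(seqs))
  comp <- utils::read.table(composition_path, header = FALSE, sep = "\t",
                            stringsAsFactors = FALSE,
                            col.names = c("name", "copies"))
  if (identical(tolower(comp$name[1]), "name")) comp <- comp[-1, , drop = FALSE]
  comp$copies <- as.integer(comp$copies)
  missing <- setdiff(comp$name, nms)
  if (length(missing))
    stop("composition names without FASTA record: ",
         paste(missing, collapse = ", "))
  lapply(seq_len(nrow(comp)), function(k) {
    chain_spec(comp$name[k],
               as.character(seqs[[match(comp$name[k], nms)]]),
               comp$copies[k])
  })
}

#' @rdname load_composition
#' @param chains list of [chain_spec()] objects to write.
#' @export
write_composition <- function(chains, fasta_path, composition_path) {
  seqs <- Biostrings::AAStringSet(vapply(chains, `[[`, "", "sequence"))
  names(seqs) <- vapply(chains, `[[`, "", "name")
  Biostrings::writeXStringSet(seqs, fasta_path)
  utils::write.table(
    data.frame(name = names(seqs),
               copies = vapply(chains, `[[`, 1L, "copies")),
    composition_path, sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = FALSE)
  invisible(c(fasta_path, composition_path))
}

#' Build the bead topology of the simulated system
#'
#' Expands the composition into one bead per residue, with consecutive
#' beads of a chain bonded, a cysteine registry and (initially empty)
#' static contact list.  Beads are numbered consecutively chain by chain.
#'
#' @param chains a list of [chain_spec()] objects (or a single one).
#' @param cfg force-field configuration, used for residue classes.
#' @return an object of class `dsb_topology`.
#' @examples
#' topo <- build_topology(chain_spec("A", "GG"))
#' topo$n          # 2 residues
#' nrow(topo$bonds)  # 1 bond
#' @export
build_topology <- function(chains, cfg = ff_config()) {
  if (inherits(chains, "chain_spec")) chains <- list(chains)
  residues <- list(); domains <- list()
  chain_id <- 0L
  for (sp in chains) {
    res <- strsplit(sp$sequence, "")[[1]]
    for (cp in seq_len(sp$copies)) {
      chain_id <- chain_id + 1L
      residues[[chain_id]] <- data.frame(
        chain = chain_id, resno = seq_along(res), type = res,
        class = unname(cfg$class[res]), species = sp$name,
        stringsAsFactors = FALSE)
      if (nrow(sp$domains))
        domains[[length(domains) + 1L]] <- data.frame(
          chain = chain_id, species = sp$name,
          start = sp$domains[, 1], end = sp$domains[, 2])
    }
  }
  residues <- do.call(rbind, residues)
  n <- nrow(residues)
  offs <- c(0L, cumsum(table(residues$chain)))
  bonds <- do.call(rbind, lapply(seq_len(chain_id), function(c) {
    idx <- which(residues$chain == c)
    if (length(idx) < 2) return(NULL)
    cbind(idx[-length(idx)], idx[-1])
  }))
  if (is.null(bonds)) bonds <- matrix(integer(0), ncol = 2)
  topo <- list(
    n = n, n_chains = chain_id,
    residues = residues,
    chain_of = residues$chain,
    bonds = bonds,
    cysteines = which(residues$type == "C"),
    static_contacts = data.frame(i = integer(0), j = integer(0),
                                 dist = numeric(0)),
    domains = if (length(domains)) do.call(rbind, domains)
              else data.frame(chain = integer(0), species = character(0),
                              start = integer(0), end = integer(0)),
    chain_offsets = offs,
    species = vapply(chains, `[[`, "", "name")
  )
  class(topo) <- "dsb_topology"
  topo
}

#' @export
print.dsb_topology <- function(x, ...) {
  ncys <- length(x$cysteines) / x$n_chains
  cat("dsb_topology:", x$n, "residues in", x$n_chains, "chains",
      sprintf("(<N> = %.1f, <n_Cys> = %.2f)\n", x$n / x$n_chains, ncys))
  invisible(x)
}

#' Summary statistics of a topology
#'
#' @param object a `dsb_topology`.
#' @param ... unused.
#' @return list with total residues `sum_N`, mean chain length `mean_N`
#'   and mean cysteines per chain `mean_n_cys`.
#' @export
summary.dsb_topology <- function(object, ...) {
  list(sum_N = object$n,
       mean_N = object$n / object$n_chains,
       mean_n_cys = length(object$cysteines) / object$n_chains)
}

#' Load a static Go-type contact map for a structured domain
#'
#' The TSV has three columns `i<TAB>j<TAB>distance_nm` with 1-based residue
#' indices *within the chain*.  Every referenced index must fall inside a
#' structured domain declared for that species, pairs must satisfy
#' |i - j| >= 3 (or be an intra-domain cysteine pair), and the native
#' distance becomes the Lennard-Jones minimum of the (permanently
#' attractive) contact.  The map is applied to every copy of the species.
#'
#' @param tsv_path contact map file.
#' @param topology a `dsb_topology` with declared domains.
#' @param species name of the chain species the map belongs to.
#' @return the topology with the static contacts appended.
#' @export
load_static_contact_map <- function(tsv_path, topology, species) {
  raw <- utils::read.table(tsv_path, header = FALSE, sep = "\t",
                           col.names = c("i", "j", "dist"))
  if (nrow(raw) == 0) return(topology)
  if (any(raw$dist <= 0)) stop("non-positive native distance in contact map")
  dom <- topology$domains[topology$domains$species == species, , drop = FALSE]
  if (nrow(dom) == 0) stop("no structured domain declared for ", species)
  chains <- unique(dom$chain)
  res <- topology$residues
  add <- list()
  for (ch in chains) {
    d <- dom[dom$chain == ch, , drop = FALSE]
    idx <- which(res$chain == ch)  # global ids ordered by resno
    for (k in seq_len(nrow(raw))) {
      i <- raw$i[k]; j <- raw$j[k]
      ini <- any(i >= d$start & i <= d$end)
      inj <- any(j >= d$start & j <= d$end)
      if (!ini || !inj)
        stop("contact map index (", i, ",", j, ") outside declared domains")
      gi <- idx[i]; gj <- idx[j]
      cys_pair <- res$type[gi] == "C" && res$type[gj] == "C"
      if (abs(i - j) < 3 && !cys_pair)
        stop("contact map pair (", i, ",", j, ") too close along the chain")
      add[[length(add) + 1L]] <-
        data.frame(i = min(gi, gj), j = max(gi, gj), dist = raw$dist[k])
    }
  }
  topology$static_contacts <- rbind(topology$static_contacts,
                                    do.call(rbind, add))
  topology
}

#' Generate an initial self-avoiding-walk conformation
#'
#' Chains are grown as self-avoiding random walks with fixed bond length
#' 0.38 nm, placed randomly in a cubic box sized to the requested density
#' (default 0.1 residues/nm^3, dilute enough that chains start out
#' monomeric).  Any non-bonded pair ends up at least 0.5 nm apart (the
#' excluded-volume cutoff).  If a walk cannot be kept inside the box it is
#' restarted and, after repeated failures, all box dimensions are grown by
#' 5%, so the realised density can be slightly below the requested one.
#'
#' @param topology a `dsb_topology`.
#' @param density requested density in residues/nm^3.
#' @param seed integer seed; the result is bit-reproducible per seed.
#' @param max_retry placement retries per bead before a chain restart.
#' @param max_restart chain restarts before the box is enlarged.
#' @param max_enlarge number of 5% box enlargements before giving up.
#' @return list with `pos` (n x 3 matrix, nm), `box` (named vector with
#'   `Lx`, `Ly`, `s`) and `density` (realised).
#' @export
generate_initial_conformation <- function(topology, density = 0.1, seed = 1,
                                          max_retry = 60L, max_restart = 40L,
                                          max_enlarge = 20L) {
  stopifnot(density > 0)
  n <- topology$n
  edge <- (n / density)^(1 / 3)
  r_b <- 0.38; r_min <- 0.5
  zmargin <- 0.5
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  for (attempt in seq_len(max_enlarge + 1L)) {
    Lx <- Ly <- s <- edge
    if (s <= 2 * zmargin + r_b)
      stop("box too small for wall margins; lower the density")
    pos <- matrix(NA_real_, n, 3)
    placed <- 0L
    ok_all <- TRUE
    for (ch in seq_len(topology$n_chains)) {
      idx <- which(topology$chain_of == ch)
      ok_chain <- FALSE
      for (restart in seq_len(max_restart)) {
        p <- matrix(NA_real_, length(idx), 3)
        p[1, ] <- c(stats::runif(1, 0, Lx), stats::runif(1, 0, Ly),
                    stats::runif(1, zmargin, s - zmargin))
        good <- placed == 0 ||
          min(.min_image_dist(p[1, , drop = FALSE],
                              pos[seq_len(placed), , drop = FALSE],
                              Lx, Ly)) >= r_min
        if (!good) next
        fail <- FALSE
        for (b in seq_along(idx)[-1]) {
          found <- FALSE
          for (try in seq_len(max_retry)) {
            u <- stats::rnorm(3)
            u <- u / sqrt(sum(u^2))
            cand <- p[b - 1, ] + r_b * u
            cand[1] <- cand[1] %% Lx
            cand[2] <- cand[2] %% Ly
            if (cand[3] < zmargin || cand[3] > s - zmargin) next
            prev <- p[seq_len(b - 2), , drop = FALSE]  # excl. bonded partner
            if (nrow(prev) &&
                min(.min_image_dist(matrix(cand, 1), prev, Lx, Ly)) < r_min)
              next
            if (placed > 0 &&
                min(.min_image_dist(matrix(cand, 1),
                                    pos[seq_len(placed), , drop = FALSE],
                                    Lx, Ly)) < r_min)
              next
            p[b, ] <- cand
            found <- TRUE
            break
          }
          if (!found) { fail <- TRUE; break }
        }
        if (!fail) { ok_chain <- TRUE; break }
      }
      if (!ok_chain) { ok_all <- FALSE; break }
      pos[idx, ] <- p
      placed <- placed + length(idx)
    }
    if (ok_all) {
      return(list(pos = pos,
                  box = c(Lx = Lx, Ly = Ly, s = s),
                  density = n / (Lx * Ly * s)))
    }
    edge <- edge * 1.05  # enlarge the box and try again
  }
  stop("failed to place the chains after ", max_enlarge, " box enlargements")
}

## pairwise distances with X/Y minimum image (rows of a vs rows of b)
.min_image_dist <- function(a, b, Lx, Ly) {
  dx <- outer(a[, 1], b[, 1], "-"); dx <- dx - Lx * round(dx / Lx)
  dy <- outer(a[, 2], b[, 2], "-"); dy <- dy - Ly * round(dy / Ly)
  dz <- outer(a[, 3], b[, 3], "-")
  sqrt(dx^2 + dy^2 + dz^2)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible()
}
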