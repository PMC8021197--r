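# System construction: compositions, bead topology, self-avoiding walks,
# static contact maps.

test_that("minimal chains produce the expected counts", {
  topo <- build_topology(chain_spec("A", "GG"))
  expect_equal(topo$n, 2)
  expect_equal(nrow(topo$bonds), 1)
  expect_length(topo$cysteines, 0)

  topo2 <- build_topology(chain_spec("B", "QCQGQCQGQG", copies = 2))
  expect_equal(topo2$n, 20)
  expect_length(topo2$cysteines, 4)
  expect_equal(nrow(topo2$bonds), 2 * 9)  # sum over chains of (N_c - 1)
})

test_that("illegal input is rejected", {
  expect_error(chain_spec("x", ""), "empty")
  expect_error(chain_spec("x", "QXZ"), "illegal residue")
  expect_error(chain_spec("x", "QQQQQ",
                          structured_domains = list(c(1, 9))))
  expect_error(chain_spec("x", strrep("Q", 10),
                          structured_domains = list(c(1, 5), c(4, 8))),
               "overlap")
})

test_that("composition files round-trip the summary statistics", {
  dirp <- withr::local_tempdir()
  chains <- list(chain_spec("gli", "QQPGQCQGQQPPQC", copies = 3),
                 chain_spec("glu", "GQQCPGQQSTQCAGQQCQ", copies = 2))
  write_composition(chains, file.path(dirp, "s.fasta"),
                    file.path(dirp, "c.tsv"))
  back <- load_composition(file.path(dirp, "s.fasta"),
                           file.path(dirp, "c.tsv"))
  s1 <- summary(build_topology(chains))
  s2 <- summary(build_topology(back))
  expect_identical(s1, s2)
  expect_equal(s1$sum_N, 3 * 14 + 2 * 18)
  expect_equal(s1$mean_n_cys, (3 * 2 + 2 * 3) / 5)
})

test_that("unknown composition names are an error", {
  dirp <- withr::local_tempdir()
  write_composition(list(chain_spec("a", "QQQQ")),
                    file.path(dirp, "s.fasta"), file.path(dirp, "c.tsv"))
  cat("ghost\t2\n", file = file.path(dirp, "bad.tsv"))
  expect_error(load_composition(file.path(dirp, "s.fasta"),
                                file.path(dirp, "bad.tsv")), "ghost")
})

test_that("self-avoiding walks honour bond length, clearance and the box", {
  chains <- make_toy_sequences(3, 15, 0.3, 1, seed = 5)
  topo <- build_topology(chains)
  init <- generate_initial_conformation(topo, density = 0.05, seed = 9)
  pos <- init$pos
  # bond lengths exactly 0.38 nm (minimum image across X/Y)
  dbl <- pos[topo$bonds[, 1], ] - pos[topo$bonds[, 2], ]
  dbl[, 1] <- dbl[, 1] - init$box["Lx"] * round(dbl[, 1] / init$box["Lx"])
  dbl[, 2] <- dbl[, 2] - init$box["Ly"] * round(dbl[, 2] / init$box["Ly"])
  expect_equal(sqrt(rowSums(dbl^2)), rep(0.38, nrow(dbl)), tolerance = 1e-9)
  # independent O(N^2) min-image self-avoidance check
  d <- matrix(Inf, topo$n, topo$n)
  for (i in seq_len(topo$n - 1)) for (j in (i + 1):topo$n) {
    dd <- pos[i, ] - pos[j, ]
    dd[1] <- dd[1] - init$box["Lx"] * round(dd[1] / init$box["Lx"])
    dd[2] <- dd[2] - init$box["Ly"] * round(dd[2] / init$box["Ly"])
    d[i, j] <- sqrt(sum(dd^2))
  }
  bonded <- cbind(topo$bonds[, 1], topo$bonds[, 2])
  d[bonded] <- Inf
  expect_gte(min(d), 0.5)
  # inside the box, density no higher than requested
  expect_true(all(pos[, 3] > 0 & pos[, 3] < init$box["s"]))
  expect_lte(init$density, 0.05 + 1e-12)
})

test_that("the dilute box edge follows (N/rho)^(1/3)", {
  specs <- lapply(1:16, function(k) chain_spec(paste0("c", k),
                                               strrep("Q", 219)))
  topo <- build_topology(specs)  # 3504 residues
  expect_equal(topo$n, 3504)
  expect_equal((topo$n / 0.1)^(1 / 3), 32.72, tolerance = 1e-3)
})

test_that("initial conformations are bit-reproducible per seed", {
  chains <- make_toy_sequences(2, 10, 0.3, 1, seed = 2)
  topo <- build_topology(chains)
  a <- generate_initial_conformation(topo, density = 0.05, seed = 4)
  b <- generate_initial_conformation(topo, density = 0.05, seed = 4)
  c <- generate_initial_conformation(topo, density = 0.05, seed = 5)
  expect_identical(a$pos, b$pos)
  expect_false(identical(a$pos, c$pos))
})

test_that("static contact maps are validated and set the LJ minimum", {
  dirp <- withr::local_tempdir()
  topo <- build_topology(chain_spec("s", strrep("Q", 40),
                                    structured_domains = list(c(1, 30))))
  # empty file -> no contacts
  f0 <- file.path(dirp, "empty.tsv"); file.create(f0)
  expect_equal(nrow(load_static_contact_map(f0, topo, "s")$static_contacts),
               0)
  # a valid pair is accepted with its native distance
  f1 <- file.path(dirp, "map.tsv")
  cat("5\t9\t0.62\n", file = f1)
  topo1 <- load_static_contact_map(f1, topo, "s")
  expect_equal(nrow(topo1$static_contacts), 1)
  expect_equal(topo1$static_contacts$dist, 0.62)
  # ... and enters the registry with sigma so the LJ minimum is 0.62 nm
  pos <- zigzag(40, origin = c(10, 10, 15))
  st <- md_state(topo1, pos, c(Lx = 30, Ly = 30, s = 30))
  expect_equal(st$reg$sigma * 2^(1 / 6), 0.62)
  # out-of-domain index is an error
  f2 <- file.path(dirp, "bad.tsv")
  cat("5\t35\t0.62\n", file = f2)
  expect_error(load_static_contact_map(f2, topo, "s"), "outside")
  # non-positive distance is an error
  f3 <- file.path(dirp, "neg.tsv")
  cat("5\t9\t-0.1\n", file = f3)
  expect_error(load_static_contact_map(f3, topo, "s"), "non-positive")
})
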