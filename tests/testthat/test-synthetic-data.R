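test_that("chain generator builds the expected topology", {
  # two nodes -> one edge at the spacing
  net <- make_fpu_chain(2, spacing = 5)
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$r0, 5)

  # free three-node chain -> nearest-neighbour edges only
  net3 <- make_fpu_chain(3, boundary = "free")
  expect_equal(nrow(net3$edges), 2)

  # periodic chain of N nodes -> N edges including the wrap bond
  netp <- make_fpu_chain(10, boundary = "periodic")
  expect_equal(nrow(netp$edges), 10)
  expect_equal(netp$edges$r0, rep(5, 10))

  expect_error(make_fpu_chain(1), "at least 2")
  expect_error(make_fpu_chain(2, boundary = "periodic"), "at least 3")
})

test_that("two-node spring frequency matches the closed form", {
  net <- make_fpu_chain(2, spacing = 5, k2 = 10, mass = 110)
  m <- normal_modes(net)
  expect_equal(tail(m$frequencies, 1), oracle_spring_wavenumber(10, 55),
               tolerance = 1e-8)
})

test_that("chain harmonic spectrum matches the analytic dispersion", {
  for (n in c(8, 16, 33)) {
    for (bc in c("free", "periodic")) {
      net <- make_fpu_chain(n, boundary = bc, k2 = 10, mass = 110)
      m <- normal_modes(net)
      analytic <- oracle_chain_dispersion(n, 10, 110, bc == "periodic")
      # exclude the rigid translation, where the analytic value is exactly 0
      expect_equal(m$frequencies[-1], analytic[-1], tolerance = 1e-8)
      expect_equal(m$band_edge, max(analytic), tolerance = 1e-10)
    }
  }
})

test_that("C3 trimer has the advertised count and exact symmetry", {
  tr <- make_c3_trimer(nodes_per_monomer = 20, core_nodes = 3, seed = 1)
  expect_equal(nrow(tr), 63)
  expect_equal(sum(tr$monomer == "core"), 3)

  # rotating the coordinate set by 120 degrees about the axis permutes the
  # monomers but leaves the set invariant
  xyz <- as.matrix(tr[, c("x", "y", "z")])
  R <- nnmodes:::rotation_120(c(0, 0, 1))
  rot <- xyz %*% t(R)
  for (i in seq_len(nrow(rot))) {
    dists <- sqrt(colSums((t(xyz) - rot[i, ])^2))
    expect_lt(min(dists), 1e-9)
  }

  # deterministic given the seed
  expect_identical(make_c3_trimer(seed = 4), make_c3_trimer(seed = 4))
  expect_false(isTRUE(all.equal(make_c3_trimer(seed = 4)$x,
                                make_c3_trimer(seed = 5)$x)))
  expect_error(make_c3_trimer(rotation_axis = c(0, 0, 0)), "degenerate")
})

test_that("trimer Hessian commutes with the C3 permutation-rotation", {
  for (seed in 1:3) {
    tr <- make_c3_trimer(seed = seed)
    net <- build_network(tr, r_c = 10, k2 = 10, k4 = 10)
    n <- net$n
    lab <- net$nodes$monomer
    perm <- integer(n)
    perm[lab == "M1"] <- which(lab == "M2")
    perm[lab == "M2"] <- which(lab == "M3")
    perm[lab == "M3"] <- which(lab == "M1")
    perm[lab == "core"] <- which(lab == "core")
    R <- nnmodes:::rotation_120(c(0, 0, 1))
    P <- matrix(0, 3 * n, 3 * n)
    for (i in seq_len(n)) {
      P[perm[i] + (0:2) * n, i + (0:2) * n] <- R
    }
    H <- nnm_hessian(net)
    expect_lt(norm(H %*% P - P %*% H, "F") / norm(H, "F"), 1e-12)
  }
})

test_that("toy PDB files round-trip through the structure reader", {
  tr <- make_c3_trimer(nodes_per_monomer = 4, core_nodes = 0, seed = 3)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_toy_pdb(tr, f)
  atoms <- read_pdb(f)
  expect_equal(nrow(atoms), 12)
  expect_true(all(atoms$record_kind == "ATOM"))

  cs <- coarse_grain(atoms, cg_scheme())
  ref <- tr[order(tr$chain_id, tr$residue_id), ]
  expect_equal(as.matrix(cs[, c("x", "y", "z")]),
               as.matrix(ref[, c("x", "y", "z")]),
               tolerance = 1e-3, ignore_attr = TRUE)
  # idempotence: a second write/read/coarse-grain pass is exact
  f2 <- withr::local_tempfile(fileext = ".pdb")
  write_toy_pdb(cs, f2)
  cs2 <- coarse_grain(read_pdb(f2), cg_scheme())
  expect_equal(cs2$x, cs$x, tolerance = 1e-12)
})

test_that("pigment-flagged nodes are written as configurable HETATM records", {
  s <- tibble::tibble(
    index = 1:2, x = c(0, 3), y = 0, z = 0, mass = 110, monomer = "A",
    chain_id = "A", residue_name = c("GLY", "BCL"), residue_id = 1:2,
    atom = c("CA", "MG"), kind = c("residue", "pigment"))
  f <- withr::local_tempfile(fileext = ".pdb")
  write_toy_pdb(nnmodes:::new_coarse_structure(s), f)
  lines <- readLines(f)
  expect_match(lines[2], "^HETATM")
  expect_match(lines[2], "BCL")
})

test_that("vibronic fixtures cover the analytic limits", {
  mono <- make_vibronic_fixture("monomer", eps = 12300, omega = 100, S = 0.3)
  expect_equal(length(mono$site_energies), 1)
  expect_equal(mono$coupled_sites, 1L)

  # degenerate dimer, S = 0: sticks split by exactly 2J
  d <- make_vibronic_fixture("dimer", J = 50, S = 0, n_levels = 1)
  st <- stick_transitions(d)
  expect_equal(diff(st$energy), 100, tolerance = 1e-10)

  # J = 0 dimer: spectrum is the sum of the two monomer spectra
  d0 <- make_vibronic_fixture("dimer", eps = c(12200, 12400), J = 0, S = 0.3)
  g <- seq(11900, 12900, length.out = 201)
  spd <- broaden_and_average(d0, g, fwhm_disorder = 0, n_realisations = 1)
  sm <- broaden_and_average(make_vibronic_fixture("monomer", eps = 12200,
                                                  S = 0.3),
                            g, fwhm_disorder = 0, n_realisations = 1)$la +
    broaden_and_average(make_vibronic_fixture("monomer", eps = 12400,
                                              S = 0.3),
                        g, fwhm_disorder = 0, n_realisations = 1)$la
  expect_equal(spd$la, sm, tolerance = 1e-10)

  h <- make_vibronic_fixture("heptamer")
  expect_equal(length(h$site_energies), 7)
  expect_equal(h$coupled_sites, c(3L, 4L, 7L))
  expect_error(make_vibronic_fixture("octamer"))
})
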