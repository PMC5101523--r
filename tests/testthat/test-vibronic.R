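test_that("the vibronic Hamiltonian is symmetric and decouples at S = 0", {
  sys <- make_vibronic_fixture("dimer", J = 50, S = 0, n_levels = 4)
  H <- build_vibronic_hamiltonian(sys)$H
  expect_equal(H, t(H))
  # block-diagonal in the vibrational level: eigenvalues are the exciton
  # energies (eps -+ J) shifted by n * omega
  ev <- sort(eigen(H, symmetric = TRUE, only.values = TRUE)$values)
  expected <- sort(as.vector(outer(c(12250, 12350), 0:3 * 100, "+")))
  expect_equal(ev, expected, tolerance = 1e-10)
})

test_that("a single coupled site reproduces the displaced-oscillator solution", {
  S <- 0.3
  omega <- 100
  eps <- 12300
  sys <- make_vibronic_fixture("monomer", eps = eps, omega = omega, S = S,
                               n_levels = 15)
  st <- stick_transitions(sys)
  # polaron-shifted ladder eps - S omega + n omega
  expect_equal(head(st$energy, 5), eps - S * omega + (0:4) * omega,
               tolerance = 1e-9)
  # Poisson Franck-Condon progression
  expect_equal(head(st$la, 4), oracle_fc(S, 0:3), tolerance = 1e-6)
  # oscillator-strength sum rule at 15 levels
  expect_equal(sum(st$la), sum(sys$dipoles^2), tolerance = 1e-3)
})

test_that("the sum rule survives coupling, disorder and any Huang-Rhys factor", {
  set.seed(20)
  sys <- make_vibronic_fixture("heptamer", S = 0.45, n_levels = 15)
  ham <- build_vibronic_hamiltonian(
    sys, site_energies = sys$site_energies + rnorm(7, 0, 40))
  st <- stick_transitions(sys, ham)
  expect_equal(sum(st$la), sum(rowSums(sys$dipoles^2)), tolerance = 1e-3)
})

test_that("spectra are converged at 15 oscillator levels", {
  g <- seq(11800, 12800, length.out = 401)
  sp <- lapply(c(15, 25), function(L) {
    sys <- make_vibronic_fixture("dimer", J = 30, S = 0.3, n_levels = L)
    broaden_and_average(sys, g, fwhm_disorder = 0, n_realisations = 1)
  })
  rel <- sum(abs(sp[[1]]$la - sp[[2]]$la)) / sum(abs(sp[[2]]$la))
  expect_lt(rel, 1e-3)
})

test_that("a degenerate parallel-dipole dimer has one dark state", {
  d <- make_vibronic_fixture("dimer", J = 50, S = 0, n_levels = 1)
  st <- stick_transitions(d)
  expect_equal(sort(st$la), c(0, 2), tolerance = 1e-10)
  # the bright state sits at eps + J for parallel dipoles
  expect_equal(st$energy[st$la > 1], 12350)
})

test_that("coplanar dipoles through a common plane carry no rotational strength", {
  sys <- exciton_system(
    site_energies = c(12250, 12350, 12300),
    couplings = matrix(c(0, 30, 10, 30, 0, 20, 10, 20, 0), 3, 3),
    dipoles = rbind(c(1, 0, 0), c(0.3, 1, 0), c(-1, 0.4, 0)),
    positions = rbind(c(0, 0, 0), c(8, 2, 0), c(3, -5, 0)),
    mode_frequency = 100, huang_rhys = 0.2, coupled_sites = 1:3,
    n_levels = 8)
  st <- stick_transitions(sys)
  expect_lt(max(abs(st$cd)), 1e-12)
})

test_that("linear dichroism follows the axis-angle convention", {
  # dipole along the symmetry axis: LD = |mu|^2 (1 - 3) = -2 |mu|^2
  sys <- exciton_system(12300, matrix(0, 1, 1), dipoles = c(0, 0, 1),
                        positions = c(0, 0, 0), huang_rhys = 0,
                        n_levels = 1, symmetry_axis = c(0, 0, 1))
  st <- stick_transitions(sys)
  expect_equal(st$ld, -2 * st$la)
  # perpendicular dipole: LD = +|mu|^2
  sysp <- exciton_system(12300, matrix(0, 1, 1), dipoles = c(1, 0, 0),
                         positions = c(0, 0, 0), huang_rhys = 0,
                         n_levels = 1, symmetry_axis = c(0, 0, 1))
  expect_equal(stick_transitions(sysp)$ld, stick_transitions(sysp)$la)
})

test_that("disorder averaging is seeded and has the exact zero-width limit", {
  sys <- make_vibronic_fixture("dimer", J = 40, S = 0.3)
  g <- seq(11900, 12800, length.out = 301)
  a <- broaden_and_average(sys, g, n_realisations = 25, seed = 42)
  b <- broaden_and_average(sys, g, n_realisations = 25, seed = 42)
  expect_identical(a$la, b$la)
  c2 <- broaden_and_average(sys, g, n_realisations = 25, seed = 43)
  expect_false(identical(a$la, c2$la))

  clean <- broaden_and_average(sys, g, fwhm_disorder = 0, n_realisations = 1)
  one <- broaden_and_average(sys, g, fwhm_disorder = 0, n_realisations = 3)
  expect_equal(one$la, clean$la, tolerance = 1e-12)
})

test_that("disorder preserves the spectral first moment and widens the line", {
  sys <- make_vibronic_fixture("monomer", eps = 12300, omega = 100, S = 0.3)
  g <- seq(11000, 13600, length.out = 1301)
  clean <- broaden_and_average(sys, g, fwhm_disorder = 0, n_realisations = 1)
  n_real <- 400
  dis <- broaden_and_average(sys, g, fwhm_disorder = 100,
                             n_realisations = n_real, seed = 9)
  # Gaussian site-energy scatter is symmetric: the first moment is unbiased;
  # 3 sigma Monte-Carlo band with sigma_mean = fwhm/2.355/sqrt(n)
  mc_sigma <- 100 / 2.355 / sqrt(n_real)
  expect_lt(abs(spectrum_first_moment(dis) - spectrum_first_moment(clean)),
            3 * mc_sigma)

  wider <- broaden_and_average(sys, g, fwhm_disorder = 200,
                               n_realisations = n_real, seed = 9)
  spec_var <- function(sp) {
    mu <- spectrum_first_moment(sp)
    sum((sp$wavenumber - mu)^2 * sp$la) / sum(sp$la)
  }
  expect_gt(spec_var(wider), spec_var(dis))
})

test_that("mode placement variants behave in the analytic limits", {
  sys <- make_vibronic_fixture("heptamer", S = 0.3)
  g <- seq(11900, 12800, length.out = 121)
  # S = 0: the three placements give identical spectra
  sys0 <- sys
  sys0$huang_rhys <- rep(0, 7)
  cmp0 <- compare_mode_placement(sys0, g, mode_frequencies = 100,
                                 fwhm_disorder = 0, n_realisations = 1)
  la0 <- split(cmp0$la, cmp0$variant)
  expect_equal(la0$none, la0$subset, tolerance = 1e-10)
  expect_equal(la0$none, la0$all, tolerance = 1e-10)

  # coupling the mode red-shifts the lowest exciton (polaron stabilisation)
  low_stick <- function(sites) {
    s <- sys
    s$coupled_sites <- sites
    stick_transitions(s)$energy[1]
  }
  expect_lt(low_stick(c(3L, 4L, 7L)), low_stick(integer(0)))

  # uniform decoupled sites with the mode everywhere: intensity-summed
  # replica of the single-site spectrum
  uni <- exciton_system(rep(12300, 3), matrix(0, 3, 3),
                        dipoles = rbind(c(1, 0, 0), c(1, 0, 0), c(1, 0, 0)),
                        positions = matrix(0, 3, 3), mode_frequency = 100,
                        huang_rhys = 0.3, coupled_sites = 1:3, n_levels = 12)
  gu <- seq(11900, 12900, length.out = 201)
  su <- broaden_and_average(uni, gu, fwhm_disorder = 0, n_realisations = 1)
  s1 <- broaden_and_average(make_vibronic_fixture("monomer", eps = 12300,
                                                  S = 0.3, n_levels = 12),
                            gu, fwhm_disorder = 0, n_realisations = 1)
  expect_equal(su$la, 3 * s1$la, tolerance = 1e-8)
})
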