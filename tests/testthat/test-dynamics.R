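test_that("velocity-kick excitation carries exactly the requested energy", {
  net <- make_fpu_chain(16, boundary = "periodic")
  m <- normal_modes(net)
  st <- excite(net, m, mode_rank = 1, e0 = 40)
  ke <- 0.5 * sum(net$masses * rowSums(st$velocities^2))
  expect_equal(ke, 40, tolerance = 1e-10)
  expect_equal(st$coords, net$coords)
  expect_equal(potential_energy(net, st$coords), 0)
  expect_error(excite(net, m, e0 = 0), "positive")
})

test_that("displacement excitation matches the requested potential energy", {
  net <- make_fpu_chain(16, boundary = "periodic", k4 = 10)
  m <- normal_modes(net)
  st <- excite(net, m, mode_rank = 1, e0 = 25, protocol = "displacement")
  expect_equal(max(abs(st$velocities)), 0)
  expect_equal(potential_energy(net, st$coords), 25, tolerance = 1e-8)
})

test_that("opposite excitation signs give mirror trajectories when harmonic", {
  net <- make_fpu_chain(8, k4 = 0)
  m <- normal_modes(net)
  tp <- integrate_dynamics(net, excite(net, m, e0 = 2, sign = 1), 500,
                           stride = 50)
  tm <- integrate_dynamics(net, excite(net, m, e0 = 2, sign = -1), 500,
                           stride = 50)
  eq <- rep(as.vector(net$coords), each = length(tp$times_fs))
  expect_equal(as.vector(tp$positions) - eq, -(as.vector(tm$positions) - eq),
               tolerance = 1e-10)
})

test_that("a harmonic spring follows the cosine closed form", {
  net <- make_fpu_chain(2, k2 = 10, k4 = 0)
  m <- normal_modes(net)
  st <- excite(net, m, e0 = 1, protocol = "displacement")
  # 10 periods of the 46.3 cm^-1 mode at a fine step
  period_fs <- 1 / (oracle_spring_wavenumber(10, 55) * 2.99792458e10) * 1e15
  tr <- integrate_dynamics(net, st, n_steps = round(10 * period_fs / 0.05),
                           dt_fs = 0.05, stride = 1000, probe_nodes = 1)
  p <- probe_trace(tr, 1)
  A <- p$value[1] - net$coords[1, 1]
  omega_fs <- 2 * pi * oracle_spring_wavenumber(10, 55) * 2.99792458e10 * 1e-15
  pred <- net$coords[1, 1] + A * cos(omega_fs * p$time_fs)
  expect_lt(max(abs(p$value - pred)) / abs(A), 1e-6)
})

test_that("total energy is conserved over a million 1 fs steps", {
  net <- make_fpu_chain(2, k2 = 10, k4 = 10)
  m <- normal_modes(net)
  tr <- integrate_dynamics(net, excite(net, m, e0 = 5), n_steps = 1e6,
                           stride = 1000)
  expect_lt(glance(tr)$max_rel_drift, 1e-3)
})

test_that("integration is time-reversible", {
  net <- make_fpu_chain(12, boundary = "periodic", k4 = 10)
  m <- normal_modes(net)
  st <- excite(net, m, e0 = 10)
  fw <- integrate_dynamics(net, st, n_steps = 2e4, stride = 2e4)
  last <- length(fw$times_fs)
  back <- integrate_dynamics(net, list(
    coords = matrix(fw$positions[last, , ], net$n, 1),
    velocities = -matrix(fw$velocities[last, , ], net$n, 1)),
    n_steps = 2e4, stride = 2e4)
  lb <- length(back$times_fs)
  expect_lt(max(abs(matrix(back$positions[lb, , ], net$n, 1) - st$coords)),
            1e-6)
})

test_that("with k4 = 0 the excited mode keeps its energy", {
  net <- make_fpu_chain(32, k2 = 10, k4 = 0)
  m <- normal_modes(net)
  for (proto in c("velocity_kick", "displacement")) {
    st <- excite(net, m, mode_rank = 1, e0 = 40, protocol = proto)
    tr <- integrate_dynamics(net, st, n_steps = 10000, stride = 20)
    me <- mode_energy(tr, m, mode_rank = 1)
    expect_gt(min(me$energy / tr$total_energy), 0.999)
  }
})

test_that("node energies partition the total exactly", {
  tr3 <- make_c3_trimer(seed = 2)
  net <- build_network(tr3, r_c = 10, k2 = 10, k4 = 10)
  m <- normal_modes(net)
  tr <- integrate_dynamics(net, excite(net, m, e0 = 20), n_steps = 2000,
                           stride = 100)
  expect_equal(rowSums(tr$node_energy), tr$total_energy, tolerance = 1e-10)
  ne <- node_energies(tr)
  expect_equal(nrow(ne), length(tr$times_fs) * net$n)
  ge <- group_energies(tr, "monomer")
  tot <- tapply(ge$energy, ge$time_fs, sum)
  expect_equal(as.vector(tot), tr$total_energy, tolerance = 1e-10)

  # linear momentum stays at zero
  last <- length(tr$times_fs)
  p <- colSums(net$masses * tr$velocities[last, , ])
  expect_equal(p, c(0, 0, 0), tolerance = 1e-8)
})

test_that("a static state has zero kinetic energy everywhere", {
  net <- make_fpu_chain(5)
  tr <- integrate_dynamics(net, list(coords = net$coords,
                                     velocities = net$coords * 0),
                           n_steps = 100, stride = 10)
  expect_equal(max(abs(tr$node_energy)), 0)
  expect_equal(max(abs(displacement_map(tr)$displacement)), 0)
})

test_that("the two endpoints of a symmetric spring share energy equally", {
  net <- make_fpu_chain(2, k4 = 10)
  m <- normal_modes(net)
  tr <- integrate_dynamics(net, excite(net, m, e0 = 5), n_steps = 2000,
                           stride = 10)
  expect_equal(tr$node_energy[, 1], tr$node_energy[, 2], tolerance = 1e-10)
})

test_that("an unstable step size aborts with a diagnostic", {
  net <- make_fpu_chain(4, k2 = 10, k4 = 10)
  m <- normal_modes(net)
  st <- excite(net, m, e0 = 50)
  expect_error(integrate_dynamics(net, st, n_steps = 5000, dt_fs = 40,
                                  stride = 10),
               "energy blow-up")
})
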