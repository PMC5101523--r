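test_that("contacts follow the strict distance cutoff", {
  two <- build_network(matrix(c(0, 0, 0, 5, 0, 0), 2, 3, byrow = TRUE),
                       r_c = 10)
  expect_equal(nrow(two$edges), 1)
  expect_equal(two$edges$r0, 5)

  far <- build_network(matrix(c(0, 0, 0, 12, 0, 0), 2, 3, byrow = TRUE),
                       r_c = 10)
  expect_equal(nrow(far$edges), 0)

  coll <- build_network(matrix(c(0, 6, 12), 3, 1), r_c = 10,
                        masses = rep(110, 3))
  expect_equal(nrow(coll$edges), 2)
  expect_equal(coll$edges[, c("i", "j")],
               tibble::tibble(i = 1:2, j = 2:3))

  # a pair at exactly r_c is excluded (strict inequality)
  tie <- build_network(matrix(c(0, 10), 2, 1), r_c = 10,
                       masses = c(110, 110))
  expect_equal(nrow(tie$edges), 0)
  expect_error(build_network(matrix(0, 1, 3)), "at least 2")
})

test_that("contact search agrees with the brute-force all-pairs oracle", {
  for (seed in 1:4) {
    set.seed(seed)
    coords <- matrix(runif(3 * 40, 0, 25), 40, 3)
    net <- build_network(coords, r_c = 9)
    ref <- oracle_contacts(coords, 9)
    expect_equal(as.matrix(net$edges[, c("i", "j")]),
                 ref[, 1:2, drop = FALSE], ignore_attr = TRUE)
    expect_equal(net$edges$r0, ref[, 3])
  }
  # with periodic minimum-image distances
  coords1 <- matrix(runif(30, 0, 60), 30, 1)
  netp <- build_network(coords1, r_c = 9, masses = rep(1, 30), box = 60)
  refp <- oracle_contacts(coords1, 9, box = 60)
  expect_equal(as.matrix(netp$edges[, c("i", "j")]), refp[, 1:2],
               ignore_attr = TRUE)
})

test_that("pair potential evaluates the harmonic-plus-quartic form", {
  net <- build_network(matrix(c(0, 5), 2, 1), r_c = 10, k2 = 10, k4 = 10,
                       masses = c(110, 110))
  expect_equal(potential_energy(net), 0)
  # stretch +1 A: k2/2 + k4/4 = 5 + 2.5
  expect_equal(potential_energy(net, matrix(c(0, 6), 2, 1)), 7.5)
  # compression is symmetric (even powers)
  expect_equal(potential_energy(net, matrix(c(0, 4), 2, 1)), 7.5)
  expect_error(potential_energy(net, matrix(c(0, NaN), 2, 1)), "finite")
})

test_that("with k4 = 0 the potential is exactly harmonic", {
  net <- random_blob_network(10, seed = 2, k4 = 0)
  set.seed(11)
  dx <- matrix(rnorm(30, 0, 0.05), 10, 3)
  v1 <- potential_energy(net, net$coords + dx)
  v2 <- potential_energy(net, net$coords + 2 * dx)
  # quadratic scaling holds to the size of the cubic geometric correction
  expect_equal(v2 / v1, 4, tolerance = 0.02)
})

test_that("forces are the exact gradient and respect Newton's third law", {
  net <- random_blob_network(12, seed = 3)
  expect_equal(max(abs(network_forces(net))), 0)

  set.seed(5)
  coords <- net$coords + matrix(rnorm(36, 0, 0.2), 12, 3)
  f <- network_forces(net, coords)
  fd <- oracle_fd_forces(net, coords)
  expect_equal(f, fd, tolerance = 1e-6)
  expect_equal(colSums(f), c(0, 0, 0), tolerance = 1e-12)
  # net torque about the origin vanishes
  torque <- colSums(cbind(
    coords[, 2] * f[, 3] - coords[, 3] * f[, 2],
    coords[, 3] * f[, 1] - coords[, 1] * f[, 3],
    coords[, 1] * f[, 2] - coords[, 2] * f[, 1]))
  expect_equal(torque, c(0, 0, 0), tolerance = 1e-10)

  pair <- build_network(matrix(c(0, 0, 0, 4, 1, 2), 2, 3, byrow = TRUE),
                        r_c = 10)
  fp <- network_forces(pair, pair$coords + c(0.3, 0, 0, 0, 0, 0))
  expect_equal(fp[1, ], -fp[2, ], tolerance = 1e-12)
})

test_that("energy is invariant under global rotation and translation", {
  net <- random_blob_network(10, seed = 7)
  set.seed(8)
  coords <- net$coords + matrix(rnorm(30, 0, 0.3), 10, 3)
  v0 <- potential_energy(net, coords)
  shifted <- sweep(coords, 2, c(3, -2, 7), "+")
  expect_equal(potential_energy(net, shifted), v0, tolerance = 1e-12)
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  expect_equal(potential_energy(net, coords %*% t(R)), v0, tolerance = 1e-9)
})

test_that("networks round-trip through the text serialisation", {
  net <- random_blob_network(9, seed = 9)
  f <- withr::local_tempfile(fileext = ".txt")
  write_network(net, f)
  back <- read_network(f)
  expect_equal(back$edges, net$edges)
  expect_equal(back$coords, net$coords, ignore_attr = TRUE)
  expect_equal(back$k2, net$k2)
  expect_equal(back$masses, net$masses)
  # a periodic network keeps its box
  ch <- make_fpu_chain(8, boundary = "periodic")
  f2 <- withr::local_tempfile(fileext = ".txt")
  write_network(ch, f2)
  expect_equal(read_network(f2)$box, ch$box)
})
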