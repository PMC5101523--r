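#' Excite a normal mode with a prescribed total energy
#'
#' Prepares an initial condition whose total energy (kinetic + potential)
#' equals `e0`, directed along one eigenvector of the harmonic spectrum.  Two
#' protocols are available.  `velocity_kick` (default): nodes start at
#' equilibrium with velocities proportional to the mass-unweighted eigenvector
#' pattern, scaled so the kinetic energy is exactly `e0`; this sidesteps any
#' ambiguity about the anharmonic potential energy at finite displacement.
#' `displacement`: nodes start at rest, displaced along the mode until the
#' (generally anharmonic) potential energy equals `e0` (solved numerically).
#'
#' @param network an `elastic_network`
#' @param modes its `normal_mode_set`
#' @param mode_rank which mode, counted from the top of the spectrum
#'   (1 = highest frequency)
#' @param e0 total excitation energy, kcal/mol
#' @param protocol `"velocity_kick"` or `"displacement"`
#' @param sign overall sign of the excitation (+1 or -1); with `k4 = 0` the
#'   two signs give mirror-image trajectories
#' @param perturbation optional relative amplitude of a seeded random
#'   velocity perturbation (e.g. `1e-3`).  A mode that is an exact nonlinear
#'   solution (the chain's zone-boundary mode, a trimer's symmetric mode)
#'   only sheds energy through its modulational instability, which a small
#'   broadband perturbation triggers reproducibly instead of leaving it to
#'   round-off noise.  The state is rescaled so the total energy is still
#'   exactly `e0`.
#' @param seed RNG seed for the perturbation
#' @return a list with `coords`, `velocities`, `mode_rank`, `protocol`,
#'   `e0` and the eigenvector `sign` convention actually used
#' @export
excite <- function(network, modes, mode_rank = 1, e0 = 40,
                   protocol = c("velocity_kick", "displacement"), sign = 1,
                   perturbation = 0, seed = 1) {
  protocol <- match.arg(protocol)
  if (!is.finite(e0) || e0 <= 0) abort("e0 must be positive")
  stopifnot(sign %in% c(-1, 1), perturbation >= 0)
  idx <- mode_index_from_top(modes, mode_rank)
  ev <- modes$vectors[, idx]
  n <- network$n
  d <- network$d
  # real-space displacement pattern: un-mass-weighted eigenvector
  pattern <- matrix(ev / sqrt(rep(network$masses, d)), nrow = n, ncol = d)

  if (protocol == "velocity_kick") {
    # KE of alpha * pattern is alpha^2 / 2 because the eigenvector is
    # orthonormal in the mass metric
    alpha <- sign * sqrt(2 * e0)
    coords <- network$coords
    vel <- alpha * pattern
  } else {
    vfun <- function(a) {
      potential_energy(network, network$coords + a * pattern) - e0
    }
    upper <- 1
    while (vfun(upper) < 0) upper <- upper * 2
    alpha <- sign * uniroot(vfun, c(0, upper), tol = 1e-12)$root
    coords <- network$coords + alpha * pattern
    vel <- matrix(0, n, d)
  }
  if (perturbation > 0) {
    set.seed(seed)
    noise <- matrix(rnorm(n * d), n, d) / sqrt(network$masses)
    ke_noise <- 0.5 * sum(network$masses * rowSums(noise^2))
    vel <- vel + perturbation * sqrt(e0 / ke_noise) * noise
    # rescale velocities so kinetic + potential energy is exactly e0 again
    ke <- 0.5 * sum(network$masses * rowSums(vel^2))
    pe <- potential_energy(network, coords)
    if (ke > 0 && e0 > pe) vel <- vel * sqrt((e0 - pe) / ke)
  }
  list(coords = coords, velocities = vel, mode_rank = mode_rank,
       mode_index = idx, protocol = protocol, e0 = e0, sign = sign)
}

#' Integrate the anharmonic network dynamics
#'
#' Microcanonical velocity-Verlet integration (no thermostat, no friction)
#' with a fixed time step.  The full state and per-node energies are sampled
#' every `stride` steps; designated probe nodes (all Cartesian components)
#' and the summed energy of an optional node group are recorded at every
#' step, which is what the spectral analyses need.  A per-node energy is the
#' node's kinetic energy plus half of each incident contact's potential
#' (half-bond convention), so node energies sum exactly to the total.  If the
#' total energy drifts by more than `max_drift` the run aborts with a
#' diagnostic.
#'
#' @param network an `elastic_network`
#' @param state initial condition from [excite()] (or a list with `coords`
#'   and `velocities`)
#' @param n_steps number of steps
#' @param dt_fs time step in femtoseconds (default 1)
#' @param stride full-state sampling interval in steps (default 100)
#' @param probe_nodes node indices whose coordinates are recorded every step
#' @param energy_group node indices whose summed energy is recorded every step
#' @param max_drift abort threshold on relative total-energy drift
#' @return an `nnm_trajectory`: frame times (fs), position/velocity arrays
#'   `[frame, node, component]`, per-node energies, total energy, dense probe
#'   and group-energy traces
#' @export
integrate_dynamics <- function(network, state, n_steps, dt_fs = 1,
                               stride = 100, probe_nodes = integer(0),
                               energy_group = integer(0), max_drift = 0.05) {
  if (dt_fs <= 0) abort("dt_fs must be positive")
  stopifnot(n_steps >= 1, stride >= 1)
  dt <- dt_fs / .t0_fs
  res <- nnm_verlet_cpp(state$coords, state$velocities, network$masses,
                        network$edges$i, network$edges$j, network$edges$r0,
                        network$k2, network$k4, network$box, dt,
                        as.integer(n_steps), as.integer(stride),
                        as.integer(probe_nodes), as.integer(energy_group),
                        max_drift)
  if (res$aborted_at >= 0) {
    abort(paste0("energy blow-up: total energy drifted by more than ",
                 max_drift * 100, "% of E0 at step ", res$aborted_at,
                 " (t = ", res$aborted_at * dt_fs, " fs); ",
                 "reduce dt_fs or the excitation energy"))
  }
  nf <- res$n_frames
  structure(
    list(times_fs = res$frame_step * dt_fs,
         positions = res$positions, velocities = res$velocities,
         node_energy = res$node_energy, total_energy = res$total_energy,
         probe = res$probe, probe_nodes = as.integer(probe_nodes),
         group_energy = res$group_energy,
         energy_group = as.integer(energy_group),
         dt_fs = dt_fs, stride = stride, n_steps = n_steps,
         excitation = state[c("mode_rank", "protocol", "e0", "sign")],
         network = network),
    class = "nnm_trajectory"
  )
}

#' @export
print.nnm_trajectory <- function(x, ...) {
  cat("<nnm_trajectory> ", x$n_steps, " steps of ", x$dt_fs, " fs (",
      format(x$n_steps * x$dt_fs / 1000, digits = 4), " ps), ",
      length(x$times_fs), " frames | E(0) = ",
      format(x$total_energy[1], digits = 6), " kcal/mol\n", sep = "")
  invisible(x)
}

#' @export
glance.nnm_trajectory <- function(x, ...) {
  e0 <- x$total_energy[1]
  tibble(n_steps = x$n_steps, dt_fs = x$dt_fs, n_frames = length(x$times_fs),
         e_total = e0,
         max_rel_drift = max(abs(x$total_energy - e0)) / abs(e0))
}

#' Per-node energy time series of a trajectory
#'
#' @param trajectory an `nnm_trajectory`
#' @return a long tibble `(time_fs, node, energy)` (kcal/mol) at the
#'   trajectory's sampling stride
#' @export
node_energies <- function(trajectory) {
  en <- trajectory$node_energy
  tibble(time_fs = rep(trajectory$times_fs, ncol(en)),
         node = rep(seq_len(ncol(en)), each = nrow(en)),
         energy = as.vector(en))
}

#' @export
tidy.nnm_trajectory <- function(x, ...) node_energies(x)

#' Grouped energy time series
#'
#' Sums per-node energies over groups (for instance monomers, or a pigment's
#' nodes) at the sampling stride.
#'
#' @param trajectory an `nnm_trajectory`
#' @param groups either the name of a node-table column (e.g. `"monomer"`)
#'   or a vector of group labels, one per node
#' @return a tibble `(time_fs, group, energy)`
#' @export
group_energies <- function(trajectory, groups = "monomer") {
  if (length(groups) == 1 && is.character(groups)) {
    nodes <- trajectory$network$nodes
    if (is.null(nodes) || is.null(nodes[[groups]])) {
      abort(paste0("the network has no node column '", groups, "'"))
    }
    groups <- nodes[[groups]]
  }
  stopifnot(length(groups) == ncol(trajectory$node_energy))
  labs <- sort(unique(groups))
  agg <- vapply(labs, function(g) {
    rowSums(trajectory$node_energy[, groups == g, drop = FALSE])
  }, numeric(nrow(trajectory$node_energy)))
  tibble(time_fs = rep(trajectory$times_fs, length(labs)),
         group = rep(labs, each = length(trajectory$times_fs)),
         energy = as.vector(agg))
}

#' Energy in one harmonic mode coordinate along a trajectory
#'
#' Projects sampled states onto a mass-weighted eigenvector and returns the
#' harmonic energy in that normal coordinate,
#' `E = (1/2) qdot^2 + (1/2) omega^2 q^2`.  With `k4 = 0` the modes decouple
#' and each such energy is individually conserved.
#'
#' @param trajectory an `nnm_trajectory`
#' @param modes the `normal_mode_set` of the same network
#' @param mode_rank mode counted from the top of the spectrum
#' @return a tibble `(time_fs, energy)`
#' @export
mode_energy <- function(trajectory, modes, mode_rank = 1) {
  idx <- mode_index_from_top(modes, mode_rank)
  ev <- modes$vectors[, idx]
  omega <- wavenumber_to_omega(modes$frequencies[idx])
  net <- trajectory$network
  nf <- length(trajectory$times_fs)
  sqm <- sqrt(rep(net$masses, net$d))
  x0 <- as.vector(net$coords)
  q <- qd <- numeric(nf)
  for (f in seq_len(nf)) {
    xf <- as.vector(trajectory$positions[f, , ])
    vf <- as.vector(trajectory$velocities[f, , ])
    q[f] <- sum(ev * sqm * (xf - x0))
    qd[f] <- sum(ev * sqm * vf)
  }
  tibble(time_fs = trajectory$times_fs,
         energy = 0.5 * qd^2 + 0.5 * omega^2 * q^2)
}

#' Dense probe trace of a trajectory
#'
#' @param trajectory an `nnm_trajectory` run with `probe_nodes`
#' @param node which probe node (index into the original node numbering)
#' @param component Cartesian component (1 = x)
#' @return a tibble `(time_fs, value)` sampled every integration step
#' @export
probe_trace <- function(trajectory, node = trajectory$probe_nodes[1],
                        component = 1) {
  p <- match(node, trajectory$probe_nodes)
  if (is.na(p)) abort("node was not recorded as a probe")
  np <- length(trajectory$probe_nodes)
  col <- p + np * (component - 1)
  tibble(time_fs = seq(0, trajectory$n_steps) * trajectory$dt_fs,
         value = trajectory$probe[, col])
}

#' Dense group-energy trace
#'
#' @param trajectory an `nnm_trajectory` run with `energy_group`
#' @return a tibble `(time_fs, energy)` sampled every integration step
#' @export
group_energy_trace <- function(trajectory) {
  if (length(trajectory$energy_group) == 0) {
    abort("trajectory was run without an energy_group")
  }
  tibble(time_fs = seq(0, trajectory$n_steps) * trajectory$dt_fs,
         energy = trajectory$group_energy)
}
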