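# Independent closed-form oracles, derived from CODATA constants from scratch
# (not from the package's own conversion helpers).

# frequency in cm^-1 of a harmonic oscillator with force constant k
# (kcal/mol/A^2) and reduced mass mu (amu)
oracle_spring_wavenumber <- function(k, mu) {
  kcal_per_mol_J <- 4184 / 6.02214076e23
  k_si <- k * kcal_per_mol_J / 1e-20        # J / m^2
  mu_si <- mu * 1.66053906660e-27           # kg
  omega_si <- sqrt(k_si / mu_si)            # rad / s
  omega_si / (2 * pi * 2.99792458e10)       # cm^-1
}

# analytic dispersion of the monatomic chain, in cm^-1, ascending
oracle_chain_dispersion <- function(n, k2, mass, periodic = TRUE) {
  k <- seq_len(n) - 1
  s <- if (periodic) abs(sin(pi * k / n)) else sin(pi * k / (2 * n))
  sort(2 * oracle_spring_wavenumber(k2, mass) * s)
}

# brute-force all-pairs contact list (independent of the package's search)
oracle_contacts <- function(coords, r_c, box = NULL) {
  n <- nrow(coords)
  out <- list()
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      del <- coords[i, ] - coords[j, ]
      if (!is.null(box)) del <- del - box * round(del / box)
      r <- sqrt(sum(del^2))
      if (r < r_c) out[[length(out) + 1]] <- c(i, j, r)
    }
  }
  do.call(rbind, out)
}

# central finite-difference gradient of the network potential
oracle_fd_forces <- function(network, coords, h = 1e-5) {
  f <- coords * 0
  for (i in seq_len(nrow(coords))) {
    for (c in seq_len(ncol(coords))) {
      xp <- coords; xp[i, c] <- coords[i, c] + h
      xm <- coords; xm[i, c] <- coords[i, c] - h
      f[i, c] <- -(potential_energy(network, xp) -
                     potential_energy(network, xm)) / (2 * h)
    }
  }
  f
}

# Poisson Franck-Condon progression
oracle_fc <- function(S, n) exp(-S) * S^n / factorial(n)

# small random 3-D network that is connected and at equilibrium
random_blob_network <- function(n = 12, seed = 1, k2 = 10, k4 = 10,
                                r_c = 8) {
  set.seed(seed)
  coords <- matrix(runif(3 * n, 0, 8), n, 3)
  build_network(coords, r_c = r_c, k2 = k2, k4 = k4, masses = rep(110, n))
}
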