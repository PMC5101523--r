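#' Frenkel exciton system with one discrete vibrational mode
#'
#' Container for the vibronic Hamiltonian
#' `H = sum_i eps_i |i><i| + sum_{i!=j} J_ij |i><j| + omega b'b
#'      + sum_{i in coupled} g_i |i><i| (b' + b)`,
#' with `g_i = omega sqrt(S_i)` so that the reorganisation (polaron) energy of
#' a coupled site is `S omega`.  A single shared harmonic mode is kept, with
#' `n_levels` oscillator levels (15 is converged for Huang-Rhys factors up to
#' about 0.5).  Dipole orientations and application points feed the linear
#' dichroism (angle to the symmetry axis) and circular dichroism (rotational
#' strengths).
#'
#' @param site_energies vector of site energies, cm^-1
#' @param couplings symmetric coupling matrix with zero diagonal, cm^-1
#' @param dipoles n x 3 matrix of transition dipole vectors (arbitrary units)
#' @param positions n x 3 matrix of dipole application points, angstrom
#' @param mode_frequency vibrational mode frequency omega, cm^-1
#' @param huang_rhys Huang-Rhys factor S (scalar, applied to every coupled
#'   site, or one value per site)
#' @param coupled_sites indices of the sites the mode couples to
#' @param n_levels number of oscillator levels retained
#' @param symmetry_axis unit vector of the (C3) symmetry axis used for LD
#' @return an `exciton_system`
#' @export
exciton_system <- function(site_energies, couplings, dipoles, positions,
                           mode_frequency = 100, huang_rhys = 0.3,
                           coupled_sites = seq_along(site_energies),
                           n_levels = 15, symmetry_axis = c(0, 0, 1)) {
  n <- length(site_energies)
  couplings <- as.matrix(couplings)
  dipoles <- matrix(as.numeric(dipoles), n, 3)
  positions <- matrix(as.numeric(positions), n, 3)
  if (!isTRUE(all.equal(couplings, t(couplings)))) {
    abort("coupling matrix must be symmetric")
  }
  if (any(abs(diag(couplings)) > 1e-12)) {
    abort("coupling matrix must have zero diagonal")
  }
  S <- if (length(huang_rhys) == 1) rep(huang_rhys, n) else huang_rhys
  if (length(S) != n || any(S < 0)) abort("huang_rhys must be >= 0 per site")
  if (n_levels < 1) abort("n_levels must be >= 1")
  if (length(coupled_sites) > 0) {
    stopifnot(all(coupled_sites >= 1), all(coupled_sites <= n))
  }
  axis <- symmetry_axis / sqrt(sum(symmetry_axis^2))
  structure(
    list(site_energies = as.numeric(site_energies), couplings = couplings,
         dipoles = dipoles, positions = positions,
         mode_frequency = mode_frequency, huang_rhys = S,
         coupled_sites = as.integer(coupled_sites),
         n_levels = as.integer(n_levels), symmetry_axis = axis),
    class = "exciton_system"
  )
}

#' @export
print.exciton_system <- function(x, ...) {
  cat("<exciton_system> ", length(x$site_energies), " site(s), mode ",
      x$mode_frequency, " cm^-1 on ", length(x$coupled_sites),
      " site(s) (S = ", paste(unique(x$huang_rhys[x$coupled_sites]),
                              collapse = "/"),
      "), ", x$n_levels, " levels\n", sep = "")
  invisible(x)
}

#' Build the one-exciton vibronic Hamiltonian
#'
#' Basis states are `|site i, mode level n>`, ordered site-major; the matrix
#' is real symmetric of dimension `n_sites * n_levels`.  Site energies and
#' couplings sit in each vibrational block's diagonal; the shared mode adds
#' `n omega`; linear exciton-vibrational coupling connects adjacent levels of
#' coupled sites with matrix elements `g_i sqrt(n + 1)`.
#'
#' @param system an [exciton_system()]
#' @param site_energies optional replacement site energies (used by the
#'   disorder loop)
#' @return a list with the matrix `H` and a `basis` tibble `(site, level)`
#' @export
build_vibronic_hamiltonian <- function(system, site_energies = NULL) {
  eps <- site_energies %||% system$site_energies
  ns <- length(eps)
  L <- system$n_levels
  omega <- system$mode_frequency
  g <- rep(0, ns)
  g[system$coupled_sites] <-
    omega * sqrt(system$huang_rhys[system$coupled_sites])
  dim_h <- ns * L
  H <- matrix(0, dim_h, dim_h)
  idx <- function(i, n) (i - 1L) * L + n + 1L # n = 0 .. L-1
  lev <- 0:(L - 1)
  for (i in seq_len(ns)) {
    ii <- idx(i, lev)
    H[cbind(ii, ii)] <- eps[i] + lev * omega
    if (g[i] != 0 && L > 1) {
      up <- cbind(idx(i, lev[-L]), idx(i, lev[-L] + 1))
      H[up] <- g[i] * sqrt(lev[-L] + 1)
      H[up[, 2:1, drop = FALSE]] <- H[up]
    }
    for (j in seq_len(ns)) {
      if (j != i && system$couplings[i, j] != 0) {
        H[cbind(ii, idx(j, lev))] <- system$couplings[i, j]
      }
    }
  }
  basis <- tibble(site = rep(seq_len(ns), each = L), level = rep(lev, ns))
  list(H = H, basis = basis)
}

#' Stick transitions from the vibronic ground state
#'
#' Diagonalises the one-exciton vibronic Hamiltonian and builds the
#' transitions from the global ground state `|g, n = 0>` (electronic ground
#' state, mode in its vacuum) to each vibronic eigenstate `psi`.  The
#' transition dipole is `mu_psi = sum_i <psi|i, 0> mu_i` (only the
#' zero-level components connect to the vacuum), giving linear absorption
#' `|mu_psi|^2`, linear dichroism `|mu_psi|^2 - 3 (mu_psi . axis)^2`
#' (oriented-sample convention relative to the symmetry axis), and
#' rotational strength
#' `R_psi = sum_{i<j} c_i c_j (r_i - r_j) . (mu_i x mu_j)` with
#' `c_i = <psi|i, 0>`.
#'
#' @param system an [exciton_system()]
#' @param hamiltonian optional output of [build_vibronic_hamiltonian()]
#' @return a tibble `(energy, la, ld, cd)`, one row per eigenstate, energies
#'   in cm^-1
#' @export
stick_transitions <- function(system, hamiltonian = NULL) {
  ham <- hamiltonian %||% build_vibronic_hamiltonian(system)
  eig <- eigen(ham$H, symmetric = TRUE)
  ns <- length(system$site_energies)
  L <- system$n_levels
  nstate <- ncol(eig$vectors)
  zero_rows <- (seq_len(ns) - 1L) * L + 1L # |i, n = 0> components
  C <- t(eig$vectors[zero_rows, , drop = FALSE]) # nstate x ns
  mu <- C %*% system$dipoles # nstate x 3 transition dipoles
  la <- rowSums(mu^2)
  cosax <- mu %*% system$symmetry_axis
  ld <- la - 3 * as.vector(cosax)^2
  # pairwise geometric factors (r_i - r_j) . (mu_i x mu_j)
  cd <- numeric(nstate)
  if (ns > 1) {
    for (i in seq_len(ns - 1)) {
      for (j in seq.int(i + 1, ns)) {
        mij <- c(
          system$dipoles[i, 2] * system$dipoles[j, 3] -
            system$dipoles[i, 3] * system$dipoles[j, 2],
          system$dipoles[i, 3] * system$dipoles[j, 1] -
            system$dipoles[i, 1] * system$dipoles[j, 3],
          system$dipoles[i, 1] * system$dipoles[j, 2] -
            system$dipoles[i, 2] * system$dipoles[j, 1])
        geo <- sum((system$positions[i, ] - system$positions[j, ]) * mij)
        cd <- cd + C[, i] * C[, j] * geo
      }
    }
  }
  ord <- order(eig$values)
  tibble(energy = eig$values[ord], la = la[ord], ld = ld[ord], cd = cd[ord])
}

lorentz_profile <- function(grid, center, hwhm) {
  (hwhm / pi) / ((grid - center)^2 + hwhm^2)
}

#' Disorder-averaged broadened spectra
#'
#' Monte-Carlo average over realisations of static disorder: in each
#' realisation every site energy receives an independent Gaussian shift
#' (standard deviation `fwhm / 2.355`), the vibronic Hamiltonian is
#' re-diagonalised, and each stick is dressed with a Lorentzian of half-width
#' `hwhm` (the Markovian lineshape).  The mean over realisations is returned;
#' results are reproducible for a fixed `seed`.
#'
#' @param system an [exciton_system()]
#' @param grid wavenumber grid, cm^-1
#' @param hwhm Lorentzian half-width at half-maximum per transition, cm^-1
#' @param fwhm_disorder full width at half maximum of the site-energy
#'   disorder distribution, cm^-1 (0 disables disorder)
#' @param n_realisations number of disorder realisations
#' @param seed RNG seed
#' @return a `spectrum_set` tibble `(wavenumber, la, ld, cd)` in arbitrary
#'   units, with the disorder settings as attributes
#' @export
broaden_and_average <- function(system, grid, hwhm = 10, fwhm_disorder = 100,
                                n_realisations = 1000, seed = 1) {
  stopifnot(n_realisations >= 1, hwhm > 0, fwhm_disorder >= 0)
  ns <- length(system$site_energies)
  sigma <- fwhm_disorder / (2 * sqrt(2 * log(2)))
  la <- ld <- cd <- numeric(length(grid))
  set.seed(seed)
  for (r in seq_len(n_realisations)) {
    eps <- system$site_energies + if (sigma > 0) rnorm(ns, 0, sigma) else 0
    sticks <- stick_transitions(
      system, build_vibronic_hamiltonian(system, site_energies = eps))
    prof <- vapply(seq_len(nrow(sticks)),
                   function(s) lorentz_profile(grid, sticks$energy[s], hwhm),
                   numeric(length(grid)))
    la <- la + prof %*% sticks$la
    ld <- ld + prof %*% sticks$ld
    cd <- cd + prof %*% sticks$cd
  }
  out <- tibble(wavenumber = grid, la = as.vector(la) / n_realisations,
                ld = as.vector(ld) / n_realisations,
                cd = as.vector(cd) / n_realisations)
  attr(out, "n_realisations") <- n_realisations
  attr(out, "fwhm_disorder") <- fwhm_disorder
  attr(out, "hwhm") <- hwhm
  attr(out, "seed") <- seed
  class(out) <- c("spectrum_set", class(out))
  out
}

#' Spectra for alternative mode placements
#'
#' Recomputes the disorder-averaged spectra for three variants of the same
#' exciton system - no mode coupling, mode coupled to a chosen site subset,
#' and mode coupled to every site - for each requested mode frequency, with
#' an identical disorder stream (same seed) so differences are purely the
#' mode placement.
#'
#' @param system an [exciton_system()] whose `coupled_sites` defines the
#'   subset variant
#' @param grid wavenumber grid, cm^-1
#' @param mode_frequencies mode frequencies to scan, cm^-1
#' @param ... passed to [broaden_and_average()]
#' @return a long tibble `(variant, mode_frequency, wavenumber, la, ld, cd)`
#' @export
compare_mode_placement <- function(system, grid,
                                   mode_frequencies = c(100, 180), ...) {
  ns <- length(system$site_energies)
  variants <- list(
    none = integer(0),
    subset = system$coupled_sites,
    all = seq_len(ns)
  )
  purrr::map_dfr(mode_frequencies, function(om) {
    purrr::imap_dfr(variants, function(sites, nm) {
      sys <- system
      sys$mode_frequency <- om
      sys$coupled_sites <- sites
      sp <- broaden_and_average(sys, grid, ...)
      mutate(as_tibble(sp), variant = nm, mode_frequency = om)
    })
  })[, c("variant", "mode_frequency", "wavenumber", "la", "ld", "cd")]
}

#' First moment of a spectrum
#'
#' Intensity-weighted mean wavenumber, useful for disorder-averaging checks
#' (a symmetric disorder distribution leaves the first moment at the clean
#' value).
#'
#' @param spectrum a `spectrum_set` (or tibble with `wavenumber` column)
#' @param observable column to weight by (default `"la"`)
#' @return the first moment in cm^-1
#' @export
spectrum_first_moment <- function(spectrum, observable = "la") {
  w <- spectrum[[observable]]
  sum(spectrum$wavenumber * w) / sum(w)
}

#' Peak-normalise a spectrum set
#'
#' Spectra are computed in arbitrary units; this utility rescales each
#' observable so its maximum absolute value is one, recording the factors.
#'
#' @param spectrum a `spectrum_set`
#' @return the rescaled `spectrum_set` with a `normalisation` attribute
#' @export
normalise_spectra <- function(spectrum) {
  fac <- vapply(c("la", "ld", "cd"), function(ob) {
    m <- max(abs(spectrum[[ob]]))
    if (m > 0) m else 1
  }, numeric(1))
  for (ob in names(fac)) spectrum[[ob]] <- spectrum[[ob]] / fac[ob]
  attr(spectrum, "normalisation") <- fac
  spectrum
}

#' @export
autoplot.spectrum_set <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object), c("la", "ld", "cd"),
                              names_to = "observable",
                              values_to = "intensity")
  long$observable <- factor(long$observable, c("la", "ld", "cd"),
                            c("linear absorption", "linear dichroism",
                              "circular dichroism"))
  ggplot(long, aes(x = .data$wavenumber, y = .data$intensity)) +
    geom_line() +
    facet_wrap(~observable, ncol = 1, scales = "free_y") +
    labs(x = "wavenumber (cm^-1)", y = "intensity (arb. units)")
}
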