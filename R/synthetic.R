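#' Build an anharmonic (FPU-type) chain network
#'
#' A 1-D chain of identical nodes joined by nearest-neighbour contacts with
#' the harmonic-plus-quartic pair potential - the standard testbed in which
#' discrete breathers are well characterised.  The periodic variant uses
#' minimum-image distances in a box of length `n_nodes * spacing`, so the
#' harmonic spectrum matches the analytic monatomic-chain dispersion
#' `omega(q) = sqrt(4 k2 / m) |sin(q a / 2)|` to machine precision (see
#' [chain_dispersion()]).
#'
#' @param n_nodes number of nodes (>= 2; >= 3 for periodic)
#' @param spacing equilibrium nearest-neighbour distance, angstrom
#' @param k2,k4 force constants (kcal/mol/A^2, kcal/mol/A^4)
#' @param mass node mass, amu
#' @param boundary `"free"` or `"periodic"`
#' @param r_c contact cutoff; the default (1.5 spacing) connects nearest
#'   neighbours only
#' @return an `elastic_network` with `d = 1`
#' @export
make_fpu_chain <- function(n_nodes, spacing = 5, k2 = 10, k4 = 10,
                           mass = 110, boundary = c("free", "periodic"),
                           r_c = 1.5 * spacing) {
  boundary <- match.arg(boundary)
  if (n_nodes < 2) abort("a chain needs at least 2 nodes")
  if (boundary == "periodic" && n_nodes < 3) {
    abort("a periodic chain needs at least 3 nodes")
  }
  stopifnot(spacing > 0, k2 > 0, k4 >= 0, mass > 0, r_c > spacing)
  coords <- matrix((seq_len(n_nodes) - 1) * spacing, ncol = 1)
  box <- if (boundary == "periodic") n_nodes * spacing else NULL
  build_network(coords, r_c = r_c, k2 = k2, k4 = k4,
                masses = rep(mass, n_nodes), box = box)
}

#' Analytic dispersion of the harmonic monatomic chain
#'
#' Frequencies (cm^-1, ascending) of a harmonic chain of `n_nodes` masses
#' `m` and springs `k2`: `omega_k = sqrt(4 k2 / m) |sin(pi k / n)|`
#' (periodic) or `omega_k = sqrt(4 k2 / m) sin(pi k / (2 n))`, `k = 0 .. n-1`
#' (free ends).  The independent closed-form oracle for chain mode tests;
#' the band edge is `sqrt(4 k2 / m)`.
#'
#' @param n_nodes chain length
#' @param k2 spring constant, kcal/mol/A^2
#' @param mass node mass, amu
#' @param boundary `"free"` or `"periodic"`
#' @return ascending frequencies in cm^-1
#' @export
chain_dispersion <- function(n_nodes, k2 = 10, mass = 110,
                             boundary = c("free", "periodic")) {
  boundary <- match.arg(boundary)
  k <- seq_len(n_nodes) - 1
  omega <- if (boundary == "periodic") {
    2 * sqrt(k2 / mass) * abs(sin(pi * k / n_nodes))
  } else {
    2 * sqrt(k2 / mass) * sin(pi * k / (2 * n_nodes))
  }
  sort(omega_to_wavenumber(omega))
}

# exact rotation by 120 degrees about a unit axis (Rodrigues form)
rotation_120 <- function(axis) {
  a <- axis / sqrt(sum(axis^2))
  ct <- -0.5
  st <- sqrt(3) / 2
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) * ct + st * K + (1 - ct) * tcrossprod(a)
}

#' Generate a C3-symmetric toy trimer structure
#'
#' Three identical random node clouds related by exact 120-degree rotations
#' about an axis, plus a few core nodes on the axis that contact all three
#' monomers - a minimal surrogate for a trimeric protein whose
#' highest-frequency non-degenerate modes must split equally across the
#' monomers.  The cloud is a seeded uniform blob centred `radius` angstrom
#' off the axis with half-width `blob_halfwidth`, dense enough that the
#' default 10 angstrom cutoff yields one connected network.
#'
#' @param nodes_per_monomer nodes in each monomer copy
#' @param core_nodes nodes placed on the rotation axis
#' @param rotation_axis the C3 axis (need not be normalised)
#' @param seed RNG seed (generation is deterministic given the seed)
#' @param radius distance of the blob centre from the axis, angstrom
#' @param blob_halfwidth half-width of the uniform blob, angstrom
#' @param mass node mass, amu
#' @return a `coarse_structure` with monomer labels `M1`, `M2`, `M3`,
#'   `core`
#' @export
make_c3_trimer <- function(nodes_per_monomer = 20, core_nodes = 3,
                           rotation_axis = c(0, 0, 1), seed = 1,
                           radius = 10, blob_halfwidth = 7.5, mass = 110) {
  stopifnot(nodes_per_monomer >= 1, core_nodes >= 0)
  if (sqrt(sum(rotation_axis^2)) < 1e-12) abort("degenerate rotation axis")
  a <- rotation_axis / sqrt(sum(rotation_axis^2))
  # orthonormal frame (e1, e2, a); blob sits along e1
  ref <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * a) * a
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(a[2] * e1[3] - a[3] * e1[2], a[3] * e1[1] - a[1] * e1[3],
          a[1] * e1[2] - a[2] * e1[1])
  set.seed(seed)
  local <- matrix(runif(3 * nodes_per_monomer, -blob_halfwidth,
                        blob_halfwidth), ncol = 3)
  m1 <- sweep(local, 2, c(radius, 0, 0), "+") %*%
    rbind(e1, e2, a) # rows: node coords in lab frame
  R <- rotation_120(a)
  m2 <- m1 %*% t(R)
  m3 <- m2 %*% t(R)
  core <- if (core_nodes > 0) {
    outer(seq(-3, 3, length.out = max(core_nodes, 2))[seq_len(core_nodes)], a)
  } else matrix(numeric(0), 0, 3)
  xyz <- rbind(m1, m2, m3, core)
  nodes <- tibble(
    index = seq_len(nrow(xyz)),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    mass = mass,
    monomer = c(rep(c("M1", "M2", "M3"), each = nodes_per_monomer),
                rep("core", core_nodes)),
    chain_id = c(rep(c("A", "B", "C"), each = nodes_per_monomer),
                 rep("X", core_nodes)),
    residue_name = "GLY",
    residue_id = c(rep(seq_len(nodes_per_monomer), 3), seq_len(core_nodes)),
    atom = "CA",
    kind = "residue"
  )
  nodes$source_label <- paste(nodes$residue_name, nodes$residue_id)
  new_coarse_structure(nodes, provenance = list(
    generator = "make_c3_trimer", seed = seed, axis = a))
}

#' Write a minimal PDB file for a coarse structure
#'
#' Residue nodes become fixed-column ATOM records with a CA atom name;
#' pigment-flagged nodes become HETATM records with their stored atom and
#' residue names (default `BCL` / `MG`), so toy structures exercise the
#' pigment-detection path and round-trip through [read_pdb()] /
#' [coarse_grain()] to PDB coordinate precision (1e-3 angstrom).
#'
#' @param structure a `coarse_structure`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_toy_pdb <- function(structure, path) {
  if (nrow(structure) == 0) abort("empty structure")
  s <- structure
  if (is.null(s$chain_id)) s$chain_id <- "A"
  if (is.null(s$residue_name)) {
    s$residue_name <- ifelse(s$kind == "pigment", "BCL", "GLY")
  }
  if (is.null(s$residue_id)) s$residue_id <- seq_len(nrow(s))
  if (is.null(s$atom)) s$atom <- ifelse(s$kind == "pigment", "MG", "CA")
  rec <- ifelse(s$kind == "pigment", "HETATM", "ATOM")
  name4 <- ifelse(nchar(s$atom) < 4, sprintf(" %-3s", s$atom),
                  sprintf("%-4s", s$atom))
  lines <- sprintf("%-6s%5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
                   rec, seq_len(nrow(s)), name4, s$residue_name,
                   substr(s$chain_id, 1, 1), s$residue_id,
                   s$x, s$y, s$z, 1.00, 0.00)
  con <- tryCatch(file(path, "w"),
                  error = function(e) abort(paste0("cannot write ", path)))
  on.exit(close(con))
  writeLines(c(lines, "END"), con)
  invisible(path)
}

#' Small exciton fixtures with analytically known spectra
#'
#' Ready-made [exciton_system()] objects for testing the vibronic machinery:
#' `"monomer"` is one site plus the mode (Poisson Franck-Condon progression,
#' polaron-shifted eigenvalues `eps - S omega + n omega`); `"dimer"` is two
#' sites with one coupling (stick splitting `2J` for degenerate sites, dark
#' antisymmetric state for parallel dipoles); `"heptamer"` is seven sites
#' with a user (or seeded random) coupling matrix, mirroring the pigment
#' count of an FMO monomer.
#'
#' @param kind `"monomer"`, `"dimer"` or `"heptamer"`
#' @param eps site energy (monomer) or vector of site energies, cm^-1
#' @param J dimer coupling (cm^-1) or heptamer coupling matrix
#' @param omega mode frequency, cm^-1
#' @param S Huang-Rhys factor
#' @param coupled_sites sites coupled to the mode
#' @param n_levels oscillator levels
#' @param seed seed for the heptamer's random geometry
#' @return an `exciton_system`
#' @export
make_vibronic_fixture <- function(kind = c("monomer", "dimer", "heptamer"),
                                  eps = NULL, J = NULL, omega = 100, S = 0.3,
                                  coupled_sites = NULL, n_levels = 15,
                                  seed = 1) {
  kind <- match.arg(kind)
  if (kind == "monomer") {
    eps <- eps %||% 12300
    exciton_system(eps[1], matrix(0, 1, 1),
                   dipoles = matrix(c(1, 0, 0), 1),
                   positions = matrix(0, 1, 3),
                   mode_frequency = omega, huang_rhys = S,
                   coupled_sites = coupled_sites %||% 1L,
                   n_levels = n_levels)
  } else if (kind == "dimer") {
    eps <- eps %||% c(12300, 12300)
    Jm <- matrix(c(0, J %||% 50, J %||% 50, 0), 2, 2)
    exciton_system(eps, Jm,
                   dipoles = rbind(c(1, 0, 0), c(1, 0, 0)),
                   positions = rbind(c(0, 0, 0), c(0, 0, 10)),
                   mode_frequency = omega, huang_rhys = S,
                   coupled_sites = coupled_sites %||% 1:2,
                   n_levels = n_levels)
  } else {
    eps <- eps %||% (12300 + seq(-150, 150, length.out = 7))
    set.seed(seed)
    if (is.null(J)) {
      J <- matrix(0, 7, 7)
      J[upper.tri(J)] <- runif(21, -40, 40)
      J <- J + t(J)
    }
    dip <- matrix(rnorm(21), 7, 3)
    dip <- dip / sqrt(rowSums(dip^2))
    pos <- matrix(runif(21, -15, 15), 7, 3)
    exciton_system(eps, J, dipoles = dip, positions = pos,
                   mode_frequency = omega, huang_rhys = S,
                   coupled_sites = coupled_sites %||% c(3L, 4L, 7L),
                   n_levels = n_levels)
  }
}
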