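#' Build an anharmonic elastic network from a coarse structure
#'
#' Connects every pair of nodes whose equilibrium separation is strictly less
#' than the cutoff `r_c`.  Each contact carries the pair potential
#' `V(r) = (k2/2) (r - r0)^2 + (k4/4) (r - r0)^4`, with the equilibrium length
#' `r0` taken from the input coordinates (the t = 0 geometry defines the
#' contact map, which is never updated during dynamics).  With `k4 = 0` the
#' model reduces to a classical harmonic elastic network.
#'
#' @param structure a `coarse_structure` from [coarse_grain()] (or any tibble
#'   with `x`, `y`, `z`, `mass` columns), or a plain numeric matrix of
#'   coordinates (columns = Cartesian components) with `masses` supplied
#' @param r_c contact cutoff, angstrom (default 10)
#' @param k2 harmonic force constant, kcal/mol/A^2 (default 10)
#' @param k4 quartic force constant, kcal/mol/A^4 (default 10)
#' @param masses node masses in amu (required for matrix input; default 110)
#' @param box optional periodic box lengths per dimension (minimum-image
#'   convention); `NULL` for open boundaries
#' @return an `elastic_network` object: coordinates, masses, an edge table
#'   `(i, j, r0)` and the force-field parameters
#' @export
build_network <- function(structure, r_c = 10, k2 = 10, k4 = 10,
                          masses = NULL, box = NULL) {
  if (is.matrix(structure)) {
    coords <- structure
    nodes <- NULL
    if (is.null(masses)) masses <- rep(110, nrow(coords))
  } else {
    nodes <- as_tibble(structure)
    coords <- as.matrix(nodes[, c("x", "y", "z")])
    masses <- if (!is.null(masses)) masses else nodes$mass
  }
  storage.mode(coords) <- "double"
  n <- nrow(coords)
  if (n < 2) abort("an elastic network needs at least 2 nodes")
  if (!is.finite(r_c) || r_c <= 0) abort("r_c must be positive")
  if (k2 < 0 || k4 < 0) abort("force constants must be non-negative")
  if (length(masses) != n || any(masses <= 0)) {
    abort("masses must be positive, one per node")
  }
  edges <- contact_edges(coords, r_c, box)
  new_elastic_network(coords, masses, edges, k2 = k2, k4 = k4, r_c = r_c,
                      box = box, nodes = nodes)
}

# all-pairs contact search (O(N^2); N ~ 1e3 here); strict inequality r < r_c
contact_edges <- function(coords, r_c, box = NULL) {
  n <- nrow(coords)
  d <- ncol(coords)
  dist2 <- matrix(0, n, n)
  for (c in seq_len(d)) {
    del <- outer(coords[, c], coords[, c], "-")
    if (!is.null(box) && box[c] > 0) del <- del - box[c] * round(del / box[c])
    dist2 <- dist2 + del^2
  }
  r <- sqrt(dist2)
  idx <- which(upper.tri(r) & r < r_c, arr.ind = TRUE)
  tibble(i = as.integer(idx[, 1]), j = as.integer(idx[, 2]),
         r0 = r[idx])[order(idx[, 1], idx[, 2]), ]
}

new_elastic_network <- function(coords, masses, edges, k2, k4, r_c,
                                box = NULL, nodes = NULL) {
  structure(
    list(coords = coords, masses = as.numeric(masses),
         edges = as_tibble(edges), k2 = k2, k4 = k4, r_c = r_c,
         box = if (is.null(box)) numeric(0) else as.numeric(box),
         d = ncol(coords), n = nrow(coords), nodes = nodes),
    class = "elastic_network"
  )
}

#' @export
print.elastic_network <- function(x, ...) {
  cat("<elastic_network> ", x$n, " nodes (", x$d, "-D), ", nrow(x$edges),
      " contacts | k2 = ", x$k2, ", k4 = ", x$k4, ", r_c = ", x$r_c,
      if (length(x$box) > 0) " (periodic)" else "", "\n", sep = "")
  invisible(x)
}

check_coords <- function(network, coords) {
  if (is.null(coords)) return(network$coords)
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (!all(dim(coords) == dim(network$coords))) {
    abort("coordinate dimensions do not match the network")
  }
  if (!all(is.finite(coords))) abort("non-finite coordinates")
  coords
}

#' Potential energy of an elastic network configuration
#'
#' Evaluates `V = sum over contacts of (k2/2) x^2 + (k4/4) x^4` with
#' `x = r - r0`.  Zero at the equilibrium geometry and non-negative
#' everywhere.
#'
#' @param network an `elastic_network`
#' @param coords optional coordinate matrix (defaults to equilibrium)
#' @return potential energy in kcal/mol
#' @export
potential_energy <- function(network, coords = NULL) {
  coords <- check_coords(network, coords)
  nnm_potential_cpp(coords, network$edges$i, network$edges$j,
                    network$edges$r0, network$k2, network$k4, network$box)
}

#' Forces on every node
#'
#' Analytic gradient of [potential_energy()]; forces sum to zero (translation
#' invariance) and exert no net torque.
#'
#' @inheritParams potential_energy
#' @return an n x d matrix of forces, kcal/mol/A
#' @export
network_forces <- function(network, coords = NULL) {
  coords <- check_coords(network, coords)
  nnm_forces_cpp(coords, network$edges$i, network$edges$j,
                 network$edges$r0, network$k2, network$k4, network$box)
}

#' Node degrees of an elastic network
#'
#' @param network an `elastic_network`
#' @return a tibble `(node, degree)` with the number of contacts per node
#' @export
network_degree <- function(network) {
  tibble(node = seq_len(network$n),
         degree = tabulate(c(network$edges$i, network$edges$j), network$n))
}

#' @export
tidy.elastic_network <- function(x, ...) x$edges

#' @export
glance.elastic_network <- function(x, ...) {
  tibble(n_nodes = x$n, n_edges = nrow(x$edges), k2 = x$k2, k4 = x$k4,
         r_c = x$r_c, dim = x$d, periodic = length(x$box) > 0)
}

#' Write / read an elastic network as plain text
#'
#' The file holds a commented header (force constants, cutoff, box), a node
#' block (coordinates and masses) and an edge block `(i, j, r0)`, so a
#' network round-trips exactly through `write_network()` / `read_network()`.
#'
#' @param network an `elastic_network`
#' @param path output file
#' @return `path`, invisibly (`read_network()` returns the network)
#' @export
write_network <- function(network, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# nnmodes elastic network v1",
    paste("# k2", format(network$k2, digits = 17),
          "k4", format(network$k4, digits = 17),
          "r_c", format(network$r_c, digits = 17)),
    paste(c("# box", format(network$box, digits = 17)), collapse = " "),
    paste("# nodes", network$n, "dim", network$d)), con)
  write.table(format(network$coords, digits = 17), con, row.names = FALSE,
              col.names = FALSE, quote = FALSE)
  writeLines(paste(c("# masses", format(network$masses, digits = 17)),
                   collapse = " "), con)
  writeLines(paste("# edges", nrow(network$edges)), con)
  write.table(data.frame(network$edges$i, network$edges$j,
                         format(network$edges$r0, digits = 17)),
              con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  lines <- readLines(path)
  if (!startsWith(lines[1], "# nnmodes elastic network")) {
    abort(paste0(path, " is not an nnmodes network file"))
  }
  kv <- strsplit(sub("^# ", "", lines[2]), " ")[[1]]
  k2 <- as.numeric(kv[2]); k4 <- as.numeric(kv[4]); r_c <- as.numeric(kv[6])
  box <- as.numeric(strsplit(sub("^# box ?", "", lines[3]), " ")[[1]])
  box <- box[is.finite(box)]
  nd <- as.integer(strsplit(sub("^# nodes ", "", lines[4]), " dim ")[[1]])
  n <- nd[1]; d <- nd[2]
  coords <- matrix(scan(text = lines[5:(4 + n)], quiet = TRUE), nrow = n,
                   ncol = d, byrow = TRUE)
  masses <- as.numeric(strsplit(sub("^# masses ", "", lines[5 + n]), " ")[[1]])
  ne <- as.integer(sub("^# edges ", "", lines[6 + n]))
  edges <- if (ne > 0) {
    em <- matrix(scan(text = lines[(7 + n):(6 + n + ne)], quiet = TRUE),
                 nrow = ne, ncol = 3, byrow = TRUE)
    tibble(i = as.integer(em[, 1]), j = as.integer(em[, 2]), r0 = em[, 3])
  } else tibble(i = integer(0), j = integer(0), r0 = numeric(0))
  new_elastic_network(coords, masses, edges, k2 = k2, k4 = k4, r_c = r_c,
                      box = if (length(box) == d) box else NULL)
}
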