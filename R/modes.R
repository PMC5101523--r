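#' Mass-weighted Hessian of the harmonic part of the network potential
#'
#' At the equilibrium geometry the quartic term contributes no curvature, so
#' each contact adds the rank-one block `k2 * u u^T` (with `u` the unit bond
#' vector) to the Cartesian Hessian, which is then mass-weighted as
#' `H_ab / sqrt(m_a m_b)`.  Coordinates are flattened component-major (all x,
#' then all y, then all z), matching the integrator's layout.
#'
#' @param network an `elastic_network`
#' @param mass_weighted divide by `sqrt(m_i m_j)` (default `TRUE`)
#' @return a symmetric `(n d) x (n d)` matrix
#' @export
nnm_hessian <- function(network, mass_weighted = TRUE) {
  n <- network$n
  d <- network$d
  coords <- network$coords
  box <- network$box
  H <- matrix(0, n * d, n * d)
  for (e in seq_len(nrow(network$edges))) {
    i <- network$edges$i[e]
    j <- network$edges$j[e]
    u <- coords[i, ] - coords[j, ]
    if (length(box) == d) u <- u - box * round(u / box)
    u <- u / sqrt(sum(u^2))
    K <- network$k2 * tcrossprod(u)
    ai <- i + (seq_len(d) - 1L) * n
    aj <- j + (seq_len(d) - 1L) * n
    H[ai, ai] <- H[ai, ai] + K
    H[aj, aj] <- H[aj, aj] + K
    H[ai, aj] <- H[ai, aj] - K
    H[aj, ai] <- H[aj, ai] - K
  }
  if (mass_weighted) {
    if (any(network$masses <= 0)) abort("zero or negative node mass")
    w <- 1 / sqrt(rep(network$masses, d))
    H <- H * tcrossprod(w)
  }
  H
}

#' Harmonic normal modes of an elastic network
#'
#' Diagonalises the mass-weighted Hessian.  Frequencies are the square roots
#' of the eigenvalues converted to wavenumbers (cm^-1), in ascending order;
#' eigenvectors are mass-weighted and orthonormal.  Frequencies below
#' `zero_threshold` are classified as rigid-body modes (a connected 3-D
#' network has six: three translations, three rotations).  A significantly
#' negative eigenvalue means the input geometry is not an equilibrium and is
#' an error.
#'
#' @param network an `elastic_network`
#' @param zero_threshold rigid-body classification threshold, cm^-1
#' @return a `normal_mode_set`: frequencies (cm^-1, ascending), the
#'   eigenvector matrix (columns), the band edge, and node bookkeeping
#' @export
normal_modes <- function(network, zero_threshold = 0.1) {
  H <- nnm_hessian(network)
  eig <- eigen(H, symmetric = TRUE)
  ord <- order(eig$values)
  ev <- eig$values[ord]
  vec <- eig$vectors[, ord, drop = FALSE]
  tol <- 1e-8 * max(abs(ev), 1e-12)
  if (any(ev < -tol)) {
    abort(paste0("Hessian has negative eigenvalue ", format(min(ev)),
                 ": the reference geometry is not an equilibrium"))
  }
  freq <- omega_to_wavenumber(sqrt(pmax(ev, 0)))
  structure(
    list(frequencies = freq, vectors = vec, masses = network$masses,
         n = network$n, d = network$d, band_edge = max(freq),
         rigid_body = freq < zero_threshold, nodes = network$nodes),
    class = "normal_mode_set"
  )
}

#' @export
print.normal_mode_set <- function(x, ...) {
  cat("<normal_mode_set> ", length(x$frequencies), " modes (",
      sum(x$rigid_body), " rigid-body) | band edge ",
      format(x$band_edge, digits = 6), " cm^-1\n", sep = "")
  invisible(x)
}

#' @export
tidy.normal_mode_set <- function(x, ...) {
  tibble(mode = seq_along(x$frequencies), wavenumber = x$frequencies,
         rigid_body = x$rigid_body)
}

#' @export
glance.normal_mode_set <- function(x, ...) {
  tibble(n_modes = length(x$frequencies), band_edge = x$band_edge,
         n_rigid_body = sum(x$rigid_body))
}

#' Highest non-degenerate mode
#'
#' Index (in ascending frequency order) of the highest-frequency mode that is
#' separated from both spectral neighbours by more than `gap_tol`.  In a
#' symmetric (e.g. C3) structure the degenerate pairs mix arbitrarily in the
#' eigensolver, so symmetry statements (equal per-monomer amplitude shares)
#' only hold for the non-degenerate modes.
#'
#' @param modes a `normal_mode_set`
#' @param gap_tol minimum frequency gap to both neighbours, cm^-1
#' @return an ascending-order mode index
#' @export
highest_nondegenerate_mode <- function(modes, gap_tol = 1e-4) {
  f <- modes$frequencies
  nm <- length(f)
  for (k in rev(seq_len(nm))) {
    lo <- if (k > 1) f[k] - f[k - 1] else Inf
    hi <- if (k < nm) f[k + 1] - f[k] else Inf
    if (lo > gap_tol && hi > gap_tol) return(k)
  }
  abort("no non-degenerate mode found")
}

# ascending-order index of the k-th mode counted from the top of the spectrum
mode_index_from_top <- function(modes, rank) {
  nm <- length(modes$frequencies)
  stopifnot(rank >= 1, rank <= nm)
  nm - rank + 1L
}

#' Per-node amplitude shares of a normal mode
#'
#' The share of a node is the summed squared mass-weighted eigenvector
#' amplitude over its Cartesian components; shares over all nodes sum to one
#' exactly and are invariant under eigenvector sign flips.  Per-pigment or
#' per-monomer shares are the sums over the group's nodes.
#'
#' @param modes a `normal_mode_set`
#' @param mode mode index in ascending frequency order (or, with
#'   `from_top = TRUE`, counted down from the highest-frequency mode)
#' @param from_top interpret `mode` as a rank from the top of the spectrum
#' @return a tibble `(node, share)`, joined with node labels when the network
#'   was built from a coarse structure
#' @export
mode_node_shares <- function(modes, mode = 1, from_top = FALSE) {
  if (from_top) mode <- mode_index_from_top(modes, mode)
  stopifnot(mode >= 1, mode <= length(modes$frequencies))
  v <- modes$vectors[, mode]
  share <- rowSums(matrix(v^2, nrow = modes$n, ncol = modes$d))
  out <- tibble(node = seq_len(modes$n), share = share)
  if (!is.null(modes$nodes)) {
    out <- dplyr::bind_cols(out, modes$nodes[, intersect(
      c("monomer", "kind", "residue_name", "residue_id", "source_label"),
      names(modes$nodes)), drop = FALSE])
  }
  out
}

#' Group a mode's amplitude shares
#'
#' @param modes a `normal_mode_set` built from a labelled structure
#' @param mode,from_top see [mode_node_shares()]
#' @param by grouping column of the node table (e.g. `"monomer"`) or a vector
#'   of group labels, one per node
#' @return a tibble `(group, share)` of summed shares
#' @export
mode_group_shares <- function(modes, mode = 1, from_top = FALSE,
                              by = "monomer") {
  s <- mode_node_shares(modes, mode, from_top)
  g <- if (length(by) == 1 && is.character(by)) s[[by]] else by
  if (is.null(g)) abort("no such grouping column in the node table")
  s |>
    mutate(group = g) |>
    group_by(.data$group) |>
    summarise(share = sum(.data$share), .groups = "drop")
}

#' Node degree versus mean amplitude share over the stiffest modes
#'
#' For each node, the mean squared-amplitude share over the `top_k`
#' highest-frequency modes, joined with the node's contact degree.  High
#' frequency modes concentrate on highly connected nodes, so the profile
#' typically shows a positive degree-share correlation; with `top_k` equal to
#' the full spectrum, completeness of the eigenbasis makes the profile
#' uniform (exactly so for equal masses).
#'
#' @param network the `elastic_network` the modes came from
#' @param modes a `normal_mode_set`
#' @param top_k number of highest-frequency modes to average over
#' @return a tibble `(node, degree, mean_share)`
#' @export
degree_share_profile <- function(network, modes, top_k = 20) {
  nm <- length(modes$frequencies)
  stopifnot(top_k >= 1, top_k <= nm)
  cols <- seq.int(nm - top_k + 1L, nm)
  v2 <- modes$vectors[, cols, drop = FALSE]^2
  share <- rowSums(matrix(rowSums(v2), nrow = modes$n, ncol = modes$d)) / top_k
  left_join(network_degree(network),
            tibble(node = seq_len(modes$n), mean_share = share), by = "node")
}

#' @export
autoplot.normal_mode_set <- function(object, ...) {
  ggplot(tidy(object), aes(x = .data$wavenumber)) +
    ggplot2::geom_histogram(bins = 40) +
    labs(x = "wavenumber (cm^-1)", y = "mode count",
         title = "Harmonic mode spectrum")
}
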