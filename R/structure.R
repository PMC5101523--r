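#' Read atom records from a PDB file
#'
#' Thin wrapper around [bio3d::read.pdb()] that returns a tidy table of ATOM
#' and HETATM records.  Unknown record types (ANISOU, REMARK, ...) are
#' ignored.  Alternate-location duplicates are resolved by keeping blank or
#' "A" altloc records only.
#'
#' @param path path to a PDB-format file
#' @return a tibble with one row per atom: `record_kind`, `name`,
#'   `residue_name`, `residue_id`, `chain_id`, `x`, `y`, `z`
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) abort(paste0("PDB file not found: ", path))
  pdb <- tryCatch(
    bio3d::read.pdb(path, verbose = FALSE),
    error = function(e) abort(paste0("failed to parse PDB file ", path, ": ",
                                     conditionMessage(e)))
  )
  a <- pdb$atom
  keep <- is.na(a$alt) | a$alt %in% c("", "A")
  a <- a[keep, , drop = FALSE]
  bad <- which(!is.finite(a$x) | !is.finite(a$y) | !is.finite(a$z))
  if (length(bad) > 0) {
    abort(paste0("non-finite coordinates in PDB record(s) ",
                 paste(head(a$eleno[bad], 5), collapse = ", "), " of ", path))
  }
  tibble(
    record_kind = a$type,
    name = trimws(a$elety),
    residue_name = trimws(a$resid),
    residue_id = a$resno,
    chain_id = ifelse(is.na(a$chain) | a$chain == "", " ", a$chain),
    x = a$x, y = a$y, z = a$z
  )
}

#' Coarse-graining scheme
#'
#' Describes how atom records are reduced to network nodes: one node per
#' amino-acid residue at its C-alpha (mass 110 amu) and, for each retained
#' pigment, one node per named pigment atom.  The default pigment atoms are
#' the magnesium plus four chlorin-ring carbons and three phytol-tail carbons
#' of bacteriochlorophyll-a (MG, C2A, C2B, C2C, C2D, C2, C10, C18), eight
#' nodes chosen so the summed node mass (8 x 110 amu) approximates the
#' pigment's molecular mass.
#'
#' @param residue_mass node mass for amino-acid nodes, amu
#' @param pigment_mass node mass for pigment nodes, amu
#' @param pigment_resname residue name identifying pigment groups (HETATM)
#' @param pigment_atoms atom names retained per pigment, in node order
#' @param retained_pigments optional named list (chain id -> residue ids) of
#'   pigments to keep; by default all are kept
#' @param excluded_pigments optional named list (chain id -> residue ids) of
#'   pigments to drop (e.g. the weakly bound eighth bacteriochlorophyll of
#'   each FMO monomer); ignored when `retained_pigments` is given
#' @param monomer_map optional named character vector mapping chain ids to
#'   monomer labels; default is one monomer per chain
#' @return a list of class `cg_scheme`
#' @export
cg_scheme <- function(residue_mass = 110,
                      pigment_mass = 110,
                      pigment_resname = "BCL",
                      pigment_atoms = c("MG", "C2A", "C2B", "C2C", "C2D",
                                        "C2", "C10", "C18"),
                      retained_pigments = NULL,
                      excluded_pigments = NULL,
                      monomer_map = NULL) {
  stopifnot(residue_mass > 0, pigment_mass > 0, length(pigment_atoms) >= 1)
  structure(
    list(residue_mass = residue_mass, pigment_mass = pigment_mass,
         pigment_resname = pigment_resname, pigment_atoms = pigment_atoms,
         retained_pigments = retained_pigments,
         excluded_pigments = excluded_pigments, monomer_map = monomer_map),
    class = "cg_scheme"
  )
}

#' Coarse-grain atom records into network nodes
#'
#' Applies a [cg_scheme()]: each amino-acid residue becomes a single node of
#' mass `residue_mass` at its C-alpha position (residues without a C-alpha are
#' skipped with a warning); each retained pigment becomes one node per scheme
#' atom (a retained pigment missing any scheme atom is an error).  Waters,
#' ions and all other heteroatoms are dropped.  Node order is deterministic:
#' chain, then residue id, then pigment-atom order.
#'
#' @param atoms tibble of atom records from [read_pdb()]
#' @param scheme a [cg_scheme()]
#' @return a `coarse_structure`: a tibble with one row per node (`index`,
#'   `x`, `y`, `z`, `mass`, `monomer`, `chain_id`, `residue_name`,
#'   `residue_id`, `atom`, `kind`, `source_label`) carrying a `provenance`
#'   attribute
#' @export
coarse_grain <- function(atoms, scheme = cg_scheme()) {
  stopifnot(inherits(scheme, "cg_scheme"))
  atoms <- as_tibble(atoms)
  amino <- atoms[atoms$record_kind == "ATOM" &
                   atoms$residue_name != scheme$pigment_resname, , drop = FALSE]
  if (!any(amino$name == "CA") &&
      !any(atoms$residue_name == scheme$pigment_resname)) {
    abort("no C-alpha atoms and no pigment groups found; nothing to coarse-grain")
  }

  res_nodes <- NULL
  if (nrow(amino) > 0) {
    ca <- amino[amino$name == "CA", , drop = FALSE]
    all_res <- unique(amino[, c("chain_id", "residue_id", "residue_name")])
    got <- paste(ca$chain_id, ca$residue_id)
    missing <- all_res[!paste(all_res$chain_id, all_res$residue_id) %in% got, ,
                       drop = FALSE]
    if (nrow(missing) > 0) {
      warn(paste0(nrow(missing), " residue(s) without a C-alpha skipped: ",
                  paste(head(paste(missing$residue_name, missing$residue_id,
                                   "chain", missing$chain_id), 3),
                        collapse = "; ")))
    }
    res_nodes <- tibble(
      chain_id = ca$chain_id, residue_id = ca$residue_id,
      residue_name = ca$residue_name, atom = "CA",
      x = ca$x, y = ca$y, z = ca$z,
      mass = scheme$residue_mass, kind = "residue", atom_rank = 1L
    )
  }

  pig <- atoms[atoms$residue_name == scheme$pigment_resname, , drop = FALSE]
  pig_nodes <- NULL
  if (nrow(pig) > 0) {
    groups <- unique(pig[, c("chain_id", "residue_id")])
    keep <- rep(TRUE, nrow(groups))
    if (!is.null(scheme$retained_pigments)) {
      keep <- vapply(seq_len(nrow(groups)), function(g) {
        ids <- scheme$retained_pigments[[groups$chain_id[g]]]
        !is.null(ids) && groups$residue_id[g] %in% ids
      }, logical(1))
    } else if (!is.null(scheme$excluded_pigments)) {
      keep <- vapply(seq_len(nrow(groups)), function(g) {
        ids <- scheme$excluded_pigments[[groups$chain_id[g]]]
        is.null(ids) || !(groups$residue_id[g] %in% ids)
      }, logical(1))
    }
    groups <- groups[keep, , drop = FALSE]
    pig_nodes <- purrr::map_dfr(seq_len(nrow(groups)), function(g) {
      sub <- pig[pig$chain_id == groups$chain_id[g] &
                   pig$residue_id == groups$residue_id[g], , drop = FALSE]
      idx <- match(scheme$pigment_atoms, sub$name)
      if (anyNA(idx)) {
        abort(paste0("pigment ", scheme$pigment_resname, " ",
                     groups$residue_id[g], " chain ", groups$chain_id[g],
                     " is missing required atom(s): ",
                     paste(scheme$pigment_atoms[is.na(idx)], collapse = ", ")))
      }
      tibble(
        chain_id = sub$chain_id[idx], residue_id = sub$residue_id[idx],
        residue_name = sub$residue_name[idx], atom = sub$name[idx],
        x = sub$x[idx], y = sub$y[idx], z = sub$z[idx],
        mass = scheme$pigment_mass, kind = "pigment",
        atom_rank = seq_along(idx)
      )
    })
  }

  nodes <- bind_rows(res_nodes, pig_nodes)
  if (is.null(nodes) || nrow(nodes) == 0) abort("no nodes produced")
  nodes <- nodes[order(nodes$chain_id, nodes$residue_id, nodes$atom_rank), ,
                 drop = FALSE]
  nodes$atom_rank <- NULL

  mono <- scheme$monomer_map
  nodes$monomer <- if (is.null(mono)) nodes$chain_id else {
    unname(mono[nodes$chain_id])
  }
  nodes$source_label <- ifelse(
    nodes$kind == "residue",
    paste(nodes$residue_name, nodes$residue_id),
    paste(nodes$residue_name, nodes$residue_id, "/", nodes$atom)
  )
  nodes$index <- seq_len(nrow(nodes))
  nodes <- nodes[, c("index", "x", "y", "z", "mass", "monomer", "chain_id",
                     "residue_name", "residue_id", "atom", "kind",
                     "source_label")]
  new_coarse_structure(nodes, provenance = list(scheme = scheme))
}

new_coarse_structure <- function(nodes, provenance = list()) {
  out <- as_tibble(nodes)
  attr(out, "provenance") <- provenance
  class(out) <- c("coarse_structure", class(out))
  out
}

#' @export
print.coarse_structure <- function(x, ...) {
  cat("<coarse_structure> ", nrow(x), " nodes, ",
      length(unique(x$monomer)), " monomer(s), ",
      sum(x$kind == "pigment"), " pigment node(s)\n", sep = "")
  NextMethod()
}

# n x 3 coordinate matrix of a coarse structure
structure_coords <- function(structure) {
  as.matrix(structure[, c("x", "y", "z")])
}
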