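#' Default pipeline configuration
#'
#' A complete configuration list with the model's standard parameters:
#' cutoff 10 angstrom, k2 = 10 kcal/mol/A^2, k4 = 10 kcal/mol/A^4, 1 fs time
#' step, excitation of the highest-frequency mode with E0 = 40 kcal/mol, and
#' for spectra a Huang-Rhys factor of 0.3, 15 oscillator levels, 1000
#' disorder realisations of FWHM 100 cm^-1.  The default structure source is
#' a small anharmonic chain fixture so the configuration runs as-is.
#'
#' @param seed global seed recorded in every output
#' @return a named list understood by [validate_config()] / [run_pipeline()]
#' @export
default_config <- function(seed = 1) {
  list(
    seed = seed,
    structure = list(fixture = "fpu_chain",
                     args = list(n_nodes = 32, boundary = "periodic")),
    network = list(r_c = 10, k2 = 10, k4 = 10),
    excitation = list(mode_rank = 1, e0 = 40, protocol = "velocity_kick",
                      sign = 1),
    integration = list(dt_fs = 1, n_steps = 20000, stride = 100),
    analysis = list(window = c(5000, 20000), low_cutoff = 20),
    spectra = NULL
  )
}

#' Validate a pipeline configuration
#'
#' Checks the whole configuration and reports every violation at once rather
#' than stopping at the first.
#'
#' @param config a configuration list (see [default_config()]) or the path
#'   of a YAML file holding one
#' @return a tibble `(field, message)`; zero rows means the configuration is
#'   valid
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  v <- list()
  bad <- function(field, message) v[[length(v) + 1]] <<- tibble(
    field = field, message = message)
  num_ok <- function(x) !is.null(x) && is.numeric(x) && all(is.finite(x))

  st <- config$structure
  if (is.null(st)) bad("structure", "missing")
  else if (!is.null(st$path) && !file.exists(st$path)) {
    bad("structure.path", paste0("file does not exist: ", st$path))
  } else if (is.null(st$path) &&
             !isTRUE(st$fixture %in% c("fpu_chain", "c3_trimer"))) {
    bad("structure.fixture",
        "must be 'fpu_chain' or 'c3_trimer' (or give structure.path)")
  }
  nw <- config$network
  if (!num_ok(nw$r_c) || nw$r_c <= 0) bad("network.r_c", "must be > 0")
  if (!num_ok(nw$k2) || nw$k2 < 0) bad("network.k2", "must be >= 0")
  if (!num_ok(nw$k4) || nw$k4 < 0) bad("network.k4", "must be >= 0")
  ex <- config$excitation
  if (!num_ok(ex$e0) || ex$e0 <= 0) bad("excitation.e0", "must be > 0")
  if (!isTRUE(ex$protocol %in% c("velocity_kick", "displacement"))) {
    bad("excitation.protocol", "must be 'velocity_kick' or 'displacement'")
  }
  it <- config$integration
  if (!num_ok(it$dt_fs) || it$dt_fs <= 0) bad("integration.dt_fs", "must be > 0")
  if (!num_ok(it$n_steps) || it$n_steps < 1) {
    bad("integration.n_steps", "must be >= 1")
  }
  if (!num_ok(it$stride) || it$stride < 1) {
    bad("integration.stride", "must be >= 1")
  }
  an <- config$analysis
  if (!is.null(an$window) &&
      (!num_ok(an$window) || length(an$window) != 2 ||
         an$window[1] >= an$window[2])) {
    bad("analysis.window", "must be c(t_start, t_end) with t_start < t_end")
  }
  sp <- config$spectra
  if (!is.null(sp)) {
    if (is.null(sp$exciton)) {
      bad("spectra.exciton",
          "an exciton config (path or inline list) is required for spectra")
    } else if (is.character(sp$exciton) && !file.exists(sp$exciton)) {
      bad("spectra.exciton", paste0("file does not exist: ", sp$exciton))
    }
    if (!is.null(sp$n_realisations) &&
        (!num_ok(sp$n_realisations) || sp$n_realisations < 1)) {
      bad("spectra.n_realisations", "must be >= 1")
    }
    if (!is.null(sp$fwhm_disorder) &&
        (!num_ok(sp$fwhm_disorder) || sp$fwhm_disorder < 0)) {
      bad("spectra.fwhm_disorder", "must be >= 0")
    }
  }
  if (!num_ok(config$seed)) bad("seed", "must be a number")
  if (length(v) == 0) {
    tibble(field = character(0), message = character(0))
  } else bind_rows(v)
}

#' Run the analysis pipeline end to end
#'
#' Builds the structure (fixture generator or PDB file), constructs the
#' network, computes normal modes, integrates the excited anharmonic
#' dynamics, analyses localisation and breather formation, and (when an
#' exciton configuration is given) computes disorder-averaged spectra.
#' Every stage writes its artifact as delimited text or JSON under
#' `out_dir`, and a manifest records parameters, seed, package version and
#' file checksums, so identical configurations reproduce identical outputs
#' for the deterministic stages and for fixed-seed stochastic ones.
#'
#' @param config configuration list or YAML path (see [default_config()])
#' @param out_dir output directory (created if needed)
#' @return (invisibly) a list with the in-memory stage results and the
#'   manifest
#' @export
run_pipeline <- function(config, out_dir = tempfile("nnm_run_")) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  problems <- validate_config(config)
  if (nrow(problems) > 0) {
    abort(paste0("invalid configuration:\n", paste0(
      "  - ", problems$field, ": ", problems$message, collapse = "\n")))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  msg <- function(...) message("[nnmodes] ", ...)

  st <- config$structure
  nw <- config$network
  if (!is.null(st$path)) {
    msg("coarse-graining ", st$path)
    scheme <- do.call(cg_scheme, st$scheme %||% list())
    structure_cs <- coarse_grain(read_pdb(st$path), scheme)
    network <- build_network(structure_cs, r_c = nw$r_c, k2 = nw$k2,
                             k4 = nw$k4)
  } else if (st$fixture == "fpu_chain") {
    msg("building anharmonic chain fixture")
    args <- st$args %||% list()
    args$k2 <- nw$k2
    args$k4 <- nw$k4
    network <- do.call(make_fpu_chain, args)
  } else {
    msg("building C3 trimer fixture")
    args <- st$args %||% list()
    args$seed <- args$seed %||% config$seed
    structure_cs <- do.call(make_c3_trimer, args)
    network <- build_network(structure_cs, r_c = nw$r_c, k2 = nw$k2,
                             k4 = nw$k4)
  }
  write_network(network, file.path(out_dir, "network.txt"))

  msg("diagonalising the Hessian (", network$n * network$d, " coordinates)")
  modes <- normal_modes(network)
  write.table(tidy(modes), file.path(out_dir, "modes.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)

  ex <- config$excitation
  it <- config$integration
  state <- excite(network, modes, mode_rank = ex$mode_rank, e0 = ex$e0,
                  protocol = ex$protocol, sign = ex$sign %||% 1)
  # probe: the node carrying the largest share of the excited mode
  shares <- mode_node_shares(modes, ex$mode_rank, from_top = TRUE)
  probe <- shares$node[which.max(shares$share)]
  msg("integrating ", it$n_steps, " steps of ", it$dt_fs,
      " fs (probe node ", probe, ")")
  traj <- integrate_dynamics(network, state, n_steps = it$n_steps,
                             dt_fs = it$dt_fs, stride = it$stride,
                             probe_nodes = probe,
                             energy_group = probe)
  an <- config$analysis
  t_end <- it$n_steps * it$dt_fs
  window <- an$window %||% c(t_end / 4, t_end)
  # clamp a window that overshoots the actual run length
  if (window[1] >= t_end) window <- c(t_end / 4, t_end)
  window[2] <- min(window[2], t_end)
  ps <- power_spectrum(probe_trace(traj, probe), window = window)
  groups <- if (!is.null(network$nodes)) "monomer" else NULL
  report <- detect_breather(ps, modes, traj, window = window, groups = groups)
  write.table(as_tibble(ps), file.path(out_dir, "power_spectrum.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  write.table(displacement_map(traj, window),
              file.path(out_dir, "displacement_map.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  jsonlite::write_json(unclass(report)[!vapply(report, is.null, logical(1))],
                       file.path(out_dir, "breather_report.json"),
                       auto_unbox = TRUE, digits = NA)

  spectra <- NULL
  if (!is.null(config$spectra)) {
    sp <- config$spectra
    system <- if (is.character(sp$exciton)) {
      read_exciton_config(sp$exciton)
    } else do.call(exciton_system, sp$exciton)
    grid <- if (!is.null(sp$grid)) {
      seq(sp$grid[1], sp$grid[2], length.out = sp$grid[3] %||% 501)
    } else {
      seq(min(system$site_energies) - 400,
          max(system$site_energies) + 400, length.out = 501)
    }
    msg("computing disorder-averaged spectra (",
        sp$n_realisations %||% 1000, " realisations)")
    spectra <- broaden_and_average(
      system, grid, hwhm = sp$hwhm %||% 10,
      fwhm_disorder = sp$fwhm_disorder %||% 100,
      n_realisations = sp$n_realisations %||% 1000, seed = config$seed)
    write.table(as_tibble(spectra), file.path(out_dir, "spectra.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
  }

  files <- list.files(out_dir, full.names = TRUE)
  files <- files[!basename(files) %in% "manifest.json"]
  manifest <- list(
    package = "nnmodes",
    version = as.character(utils::packageVersion("nnmodes")),
    seed = config$seed,
    config = config,
    conventions = list(
      potential = "V = sum (k2/2) x^2 + (k4/4) x^4, x = r - r0, contacts frozen at t = 0",
      excitation = config$excitation$protocol,
      mode_coupling = "g_i = omega * sqrt(S)"),
    glance = list(network = as.list(glance(network)),
                  modes = as.list(glance(modes)),
                  trajectory = as.list(glance(traj)),
                  breather = as.list(glance(report))),
    files = setNames(as.list(unname(tools::md5sum(files))), basename(files))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(network = network, modes = modes, trajectory = traj,
                 spectrum = ps, report = report, spectra = spectra,
                 manifest = manifest, out_dir = out_dir))
}

#' Read / write an exciton configuration file
#'
#' YAML schema carrying the exciton parameters a spectra calculation needs:
#' `site_energies`, `couplings` (row list or flattened), `dipoles`,
#' `positions`, `mode_frequency`, `huang_rhys`, `coupled_sites`, `n_levels`,
#' `symmetry_axis`.  Site energies and couplings for real complexes are
#' deliberately not bundled with the package; they are user-supplied inputs.
#'
#' @param path YAML file
#' @param system an `exciton_system` (for writing)
#' @return an `exciton_system` (reading); `path` invisibly (writing)
#' @export
read_exciton_config <- function(path) {
  y <- yaml::read_yaml(path)
  n <- length(y$site_energies)
  cp <- y$couplings
  couplings <- if (is.list(cp)) do.call(rbind, cp) else matrix(unlist(cp), n, n,
                                                               byrow = TRUE)
  dip <- if (is.list(y$dipoles)) do.call(rbind, y$dipoles) else {
    matrix(unlist(y$dipoles), n, 3, byrow = TRUE)
  }
  pos <- if (is.list(y$positions)) do.call(rbind, y$positions) else {
    matrix(unlist(y$positions), n, 3, byrow = TRUE)
  }
  exciton_system(y$site_energies, couplings, dip, pos,
                 mode_frequency = y$mode_frequency %||% 100,
                 huang_rhys = y$huang_rhys %||% 0.3,
                 coupled_sites = y$coupled_sites %||% seq_len(n),
                 n_levels = y$n_levels %||% 15,
                 symmetry_axis = unlist(y$symmetry_axis) %||% c(0, 0, 1))
}

#' @rdname read_exciton_config
#' @export
write_exciton_config <- function(system, path) {
  yaml::write_yaml(list(
    site_energies = system$site_energies,
    couplings = lapply(seq_len(nrow(system$couplings)),
                       function(i) system$couplings[i, ]),
    dipoles = lapply(seq_len(nrow(system$dipoles)),
                     function(i) system$dipoles[i, ]),
    positions = lapply(seq_len(nrow(system$positions)),
                       function(i) system$positions[i, ]),
    mode_frequency = system$mode_frequency,
    huang_rhys = system$huang_rhys,
    coupled_sites = system$coupled_sites,
    n_levels = system$n_levels,
    symmetry_axis = system$symmetry_axis), path, precision = 12)
  invisible(path)
}
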