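#' Power spectrum of a densely sampled trace
#'
#' Magnitude-squared discrete Fourier transform of the mean-removed,
#' Hann-windowed trace over a time window.  The frequency axis is in
#' wavenumbers; the grid resolution is the reciprocal window length
#' (about 0.11 cm^-1 for a 300 ps window).
#'
#' @param trace a tibble `(time_fs, value)` as returned by [probe_trace()],
#'   or a numeric vector with `dt_fs` giving its sampling step
#' @param window `c(t_start, t_end)` in fs; `NULL` uses the whole trace
#' @param dt_fs sampling step when `trace` is a bare numeric vector
#' @return a `power_spectrum` tibble `(wavenumber, power)` (one-sided) with
#'   `resolution` and `window` attributes
#' @export
power_spectrum <- function(trace, window = NULL, dt_fs = NULL) {
  if (is.numeric(trace)) {
    if (is.null(dt_fs)) abort("dt_fs is required for a bare numeric trace")
    trace <- tibble(time_fs = (seq_along(trace) - 1) * dt_fs, value = trace)
  }
  names(trace)[2] <- "value"
  if (is.null(window)) window <- range(trace$time_fs)
  sel <- trace$time_fs >= window[1] & trace$time_fs <= window[2]
  if (sum(sel) < 8) abort("window lies outside (or nearly outside) the trace")
  y <- trace$value[sel]
  t <- trace$time_fs[sel]
  dt <- t[2] - t[1]
  m <- length(y)
  y <- y - mean(y)
  hann <- 0.5 * (1 - cos(2 * pi * seq(0, m - 1) / (m - 1)))
  spec <- Mod(fft(y * hann))^2
  nk <- floor(m / 2) + 1
  freq_cm <- (seq_len(nk) - 1) / (m * dt) * .cm1_per_cyc_fs
  out <- tibble(wavenumber = freq_cm, power = spec[seq_len(nk)])
  attr(out, "resolution") <- .cm1_per_cyc_fs / (m * dt)
  attr(out, "window") <- window
  attr(out, "window_variance") <- var(trace$value[sel])
  attr(out, "hann_power") <- mean(hann^2)
  class(out) <- c("power_spectrum", class(out))
  out
}

#' Locate the dominant spectral peak
#'
#' Finds the grid maximum within an optional band and refines it by quadratic
#' interpolation of log-power over the three bins around the maximum, which
#' recovers sub-bin peak positions from Hann-windowed spectra.
#'
#' @param spectrum a `power_spectrum` (or any tibble with `wavenumber` and
#'   `power` columns)
#' @param band optional `c(lo, hi)` wavenumber band to search in
#' @return a one-row tibble `(wavenumber, power)`
#' @export
spectrum_peak <- function(spectrum, band = NULL) {
  s <- spectrum
  if (!is.null(band)) {
    s <- s[s$wavenumber >= band[1] & s$wavenumber <= band[2], , drop = FALSE]
  }
  if (nrow(s) == 0) abort("empty search band")
  k <- which.max(s$power)
  nu <- s$wavenumber[k]
  if (k > 1 && k < nrow(s) && s$power[k] > 0) {
    lp <- log(pmax(s$power[(k - 1):(k + 1)], .Machine$double.xmin))
    denom <- lp[1] - 2 * lp[2] + lp[3]
    if (is.finite(denom) && denom < 0) {
      delta <- 0.5 * (lp[1] - lp[3]) / denom
      nu <- nu + delta * (s$wavenumber[k + 1] - s$wavenumber[k])
    }
  }
  tibble(wavenumber = nu, power = s$power[k])
}

#' Dominant peaks of an energy trace Fourier transform
#'
#' Transforms a mean-removed group-energy trace and reports the dominant
#' peak in the low-frequency band (below `low_cutoff`, excluding the zero
#' bin) and in the high-frequency band separately.  For an anharmonic
#' network carrying a discrete breather the high-frequency energy peak sits
#' near twice the breather's displacement frequency (the kinetic energy of a
#' harmonic oscillation at frequency omega oscillates at 2 omega).
#'
#' @param trace a tibble `(time_fs, energy)` (e.g. [group_energy_trace()])
#' @param window `c(t_start, t_end)` fs; `NULL` for the whole trace
#' @param low_cutoff boundary between the bands, cm^-1 (default 20)
#' @return a tibble `(band, wavenumber, power)` with rows `"low"`, `"high"`
#' @export
energy_fourier_peaks <- function(trace, window = NULL, low_cutoff = 20) {
  names(trace)[2] <- "value"
  ps <- power_spectrum(trace, window)
  res <- attr(ps, "resolution")
  low <- spectrum_peak(ps, band = c(2 * res, low_cutoff))
  high <- spectrum_peak(ps, band = c(low_cutoff, max(ps$wavenumber)))
  bind_rows(mutate(low, band = "low"), mutate(high, band = "high"))[,
    c("band", "wavenumber", "power")]
}

#' Participation ratio of an energy distribution
#'
#' `(sum e)^2 / (N sum e^2)`: 1 for a distribution spread uniformly over all
#' N nodes, 1/N when a single node carries everything.  Multiplied by N it
#' estimates the number of participating nodes.
#'
#' @param e non-negative energies, one per node
#' @return the participation ratio in (0, 1]
#' @export
participation_ratio <- function(e) {
  sum(e)^2 / (length(e) * sum(e^2))
}

#' Detect a discrete breather
#'
#' A discrete breather is a localised, time-periodic excitation whose
#' frequency lies strictly above the top of the harmonic spectrum, where no
#' normal mode can phase-match with it.  The detector compares the main
#' displacement peak of a probe's power spectrum with the harmonic band edge
#' and quantifies localisation of the time-averaged node-energy distribution.
#'
#' @param spectrum a `power_spectrum` of a probe displacement
#' @param modes the network's `normal_mode_set` (supplies the band edge)
#' @param trajectory the `nnm_trajectory` the spectrum came from (supplies
#'   time-averaged node energies for the localisation measures)
#' @param window analysis window `c(t_start, t_end)` fs for the energy
#'   average; `NULL` uses the spectrum's window
#' @param groups optional group labels (or node-table column name) for the
#'   dominant-group energy fraction
#' @param peak_band optional band passed to [spectrum_peak()]
#' @return a `breather_report` list: `main_peak`, `band_edge`, `gap`,
#'   `resolution`, `is_breather`, `participation_ratio`,
#'   `n_participating`, and (with `groups`) `dominant_group` /
#'   `dominant_fraction`
#' @export
detect_breather <- function(spectrum, modes, trajectory, window = NULL,
                            groups = NULL, peak_band = NULL) {
  peak <- spectrum_peak(spectrum, band = peak_band)
  res <- attr(spectrum, "resolution")
  gap <- peak$wavenumber - modes$band_edge
  if (is.null(window)) window <- attr(spectrum, "window")
  sel <- trajectory$times_fs >= window[1] & trajectory$times_fs <= window[2]
  en <- trajectory$node_energy[sel, , drop = FALSE]
  ebar <- colMeans(en)
  pr <- participation_ratio(ebar)
  # a breather pinned by structural disorder shows up in the time-averaged
  # distribution; in a translationally invariant lattice it wanders, so the
  # frame-wise (instantaneous) participation ratio is also reported
  pr_inst <- mean(apply(en, 1, participation_ratio))
  rep <- list(main_peak = peak$wavenumber, band_edge = modes$band_edge,
              gap = gap, resolution = res,
              is_breather = gap > res,
              participation_ratio = pr,
              instant_participation_ratio = pr_inst,
              n_participating = pr * length(ebar),
              n_participating_instant = pr_inst * length(ebar),
              n_nodes = length(ebar))
  if (!is.null(groups)) {
    if (length(groups) == 1 && is.character(groups)) {
      nodes <- trajectory$network$nodes
      if (is.null(nodes) || is.null(nodes[[groups]])) {
        abort(paste0("the network has no node column '", groups, "'"))
      }
      groups <- nodes[[groups]]
    }
    ge <- tapply(ebar, groups, sum)
    rep$dominant_group <- names(ge)[which.max(ge)]
    rep$dominant_fraction <- max(ge) / sum(ge)
  }
  class(rep) <- "breather_report"
  rep
}

#' @export
print.breather_report <- function(x, ...) {
  cat("<breather_report> main peak ", format(x$main_peak, digits = 6),
      " cm^-1 | band edge ", format(x$band_edge, digits = 6),
      " cm^-1 | gap ", format(x$gap, digits = 3),
      " cm^-1 -> ", if (x$is_breather) "breather" else "no breather",
      "\n  participation ratio ", format(x$participation_ratio, digits = 3),
      " (~", format(x$n_participating, digits = 3), " of ", x$n_nodes,
      " nodes)", sep = "")
  if (!is.null(x$dominant_group)) {
    cat(" | dominant group ", x$dominant_group, " (",
        format(100 * x$dominant_fraction, digits = 3), "% of energy)",
        sep = "")
  }
  cat("\n")
  invisible(x)
}

#' @export
glance.breather_report <- function(x, ...) {
  tibble(main_peak = x$main_peak, band_edge = x$band_edge, gap = x$gap,
         resolution = x$resolution, is_breather = x$is_breather,
         participation_ratio = x$participation_ratio,
         dominant_fraction = x$dominant_fraction %||% NA_real_)
}

#' Per-node mean displacement over a window
#'
#' Time-mean of `|r_i(t) - r_i(0)|` over the sampled frames inside the
#' window, keyed by node label where available; the standard way to map
#' where an excitation localises.
#'
#' @param trajectory an `nnm_trajectory`
#' @param window `c(t_start, t_end)` fs; `NULL` for the whole trajectory
#' @return a tibble `(node, displacement)` in angstrom (plus label columns)
#' @export
displacement_map <- function(trajectory, window = NULL) {
  if (is.null(window)) window <- range(trajectory$times_fs)
  sel <- which(trajectory$times_fs >= window[1] &
                 trajectory$times_fs <= window[2])
  if (length(sel) == 0) abort("window outside trajectory")
  net <- trajectory$network
  disp2 <- matrix(0, length(sel), net$n)
  for (c in seq_len(net$d)) {
    del <- matrix(trajectory$positions[sel, , c], nrow = length(sel)) -
      matrix(net$coords[, c], length(sel), net$n, byrow = TRUE)
    if (length(net$box) == net$d && net$box[c] > 0) {
      del <- del - net$box[c] * round(del / net$box[c])
    }
    disp2 <- disp2 + del^2
  }
  out <- tibble(node = seq_len(net$n),
                displacement = colMeans(sqrt(disp2)))
  if (!is.null(net$nodes)) {
    out <- dplyr::bind_cols(out, net$nodes[, intersect(
      c("monomer", "kind", "source_label"), names(net$nodes)), drop = FALSE])
  }
  out
}

#' @export
autoplot.power_spectrum <- function(object, ...) {
  ggplot(object, aes(x = .data$wavenumber, y = .data$power)) +
    geom_line() +
    labs(x = "wavenumber (cm^-1)", y = "power (arb. units)",
         title = "Displacement power spectrum")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
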