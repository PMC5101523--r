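# Internal unit system: length in angstrom, energy in kcal/mol, mass in amu.
# The derived time unit is sqrt(amu * A^2 / (kcal/mol)) ~ 48.89 fs; frequencies
# are always reported in wavenumbers (cm^-1).

.amu_kg <- 1.66053906660e-27
.kcalmol_J <- 4184 / 6.02214076e23 # one kcal/mol, per particle, in joule
.c_cm_s <- 2.99792458e10

# internal time unit in femtoseconds
.t0_fs <- sqrt(.amu_kg * 1e-20 / .kcalmol_J) * 1e15

# wavenumber (cm^-1) corresponding to unit internal angular frequency
.cm1_per_omega <- 1 / (2 * pi * .c_cm_s * .t0_fs * 1e-15)

#' Unit conversion helpers
#'
#' The package works internally in angstrom / kcal mol^-1 / amu, in which the
#' natural time unit is `sqrt(amu * A^2 / (kcal/mol))`, approximately 48.89 fs.
#' `omega_to_wavenumber()` converts an angular frequency in internal units to
#' cm^-1; `wavenumber_to_omega()` is its inverse; `internal_time_fs()` returns
#' the internal time unit in femtoseconds.
#'
#' @param omega angular frequency in internal units (rad per internal time unit)
#' @param nu wavenumber in cm^-1
#' @return a numeric vector of converted values
#' @examples
#' omega_to_wavenumber(sqrt(10 / 55)) # two 110-amu nodes on a k2 = 10 spring
#' @export
omega_to_wavenumber <- function(omega) omega * .cm1_per_omega

#' @rdname omega_to_wavenumber
#' @export
wavenumber_to_omega <- function(nu) nu / .cm1_per_omega

#' @rdname omega_to_wavenumber
#' @export
internal_time_fs <- function() .t0_fs

# frequency axis conversion for discretely sampled signals:
# cycles per femtosecond -> cm^-1
.cm1_per_cyc_fs <- 1e15 / .c_cm_s
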