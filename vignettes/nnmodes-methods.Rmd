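---
title: "Anharmonic network modes, discrete breathers and vibronic spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anharmonic network modes, discrete breathers and vibronic spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nnmodes)
```

## The model

`nnmodes` implements a nonlinear network model (NNM) of protein vibrations: a
coarse-grained structure is reduced to point nodes, and every pair of nodes
closer than a cutoff $R_c$ interacts through the pair potential

$$V \;=\; \sum_{i<j} c_{ij}\left[\tfrac{k_2}{2}\,(r_{ij}-R^0_{ij})^2
      + \tfrac{k_4}{4}\,(r_{ij}-R^0_{ij})^4\right],$$

where $c_{ij}=1$ when the *equilibrium* separation $R^0_{ij}$ (the input
geometry) is strictly below $R_c$ and $0$ otherwise.  The contact map is
frozen at $t=0$ and never updated during dynamics.  With $k_4=0$ the model is
a classical harmonic elastic network; the quartic term is what allows energy
localisation and discrete breathers (DBs).  Defaults follow the standard NNM
parameterisation for proteins: $R_c=10$ Å, $k_2=10$ kcal/mol/Å$^2$,
$k_4=10$ kcal/mol/Å$^4$, node mass 110 amu.

Units are Å, kcal/mol and amu throughout; the derived time unit is
$\sqrt{\mathrm{amu}\,\text{Å}^2/(\mathrm{kcal/mol})}\approx 48.89$ fs and all
frequencies are reported in cm$^{-1}$.  A two-node sanity check:

```{r two-node}
net <- make_fpu_chain(2, spacing = 5, k2 = 10, mass = 110)
normal_modes(net)$band_edge      # sqrt(k2 / mu), mu = 55 amu -> 46.3 cm^-1
```

### Coarse-graining

Each amino-acid residue becomes one node of mass 110 amu at its C$_\alpha$
position.  Bacteriochlorophyll pigments become eight nodes at the MG, C2A,
C2B, C2C, C2D, C2, C10 and C18 atoms — five for the chlorin ring and three
for the phytol tail, a split motivated by the fragments' relative masses.
Pigment nodes also default to 110 amu ($8\times110=880$ amu, close to the
molecular mass of the pigment); the scheme accepts a per-node override, and
the retained-pigment lists make choices such as dropping a weakly bound
eighth pigment per monomer explicit configuration rather than hidden policy.
Waters, ions and other heteroatoms are dropped.  Alternate locations keep
blank or `"A"` records.

## Normal modes

The mass-weighted Hessian of the harmonic part (the quartic term adds no
curvature at equilibrium) is assembled analytically — each contact
contributes $k_2\,\hat u\hat u^{\mathsf T}$ with $\hat u$ the unit bond
vector — and diagonalised densely (`eigen`, LAPACK); at the sizes this model
targets (~1200 nodes, 3N ≈ 3700) this takes seconds, so no sparse or partial
solver is used.  Frequencies below 0.1 cm$^{-1}$ are classified rigid-body —
far below any physical mode at these parameters; a connected 3-D network has
exactly six.  A significantly negative eigenvalue is treated as an error
(the input was not an equilibrium geometry).

Per-node *amplitude shares* are the summed squared components of the
**mass-weighted** eigenvector on a node; with this convention shares sum to
exactly one, and with near-uniform masses the distinction from Cartesian
amplitudes is negligible.  Degenerate pairs (the rule, not the exception, in
a C3-symmetric trimer) mix arbitrarily in the solver, so symmetry statements
are made about non-degenerate modes (`highest_nondegenerate_mode()`);
per-monomer shares of those are equal to machine precision.

## Anharmonic dynamics

Dynamics are microcanonical velocity-Verlet at a 1 fs default step (about
1/2000 of the band-edge period), with no thermostat or friction.  The
symplectic integrator bounds the energy error: drift over $10^6$ steps is
below 0.01% in the test systems, and a run aborts with a diagnostic if the
total energy moves by more than 5%.

A mode is excited with total energy $E_0$ by one of two protocols.  The
default `velocity_kick` starts from equilibrium with velocities along the
(un-mass-weighted) eigenvector pattern scaled so the kinetic energy is
exactly $E_0$; this avoids any ambiguity about anharmonic potential energy
at finite displacement.  The `displacement` protocol instead displaces along
the mode until the potential energy equals $E_0$ (solved numerically).

Two storage rates are used deliberately: the full state and per-node
energies (kinetic plus half of each incident bond's potential, so node
energies sum exactly to the total) are sampled every `stride` steps, while
designated probe coordinates and one group-energy trace are recorded at
every step — the spectral analyses need dense traces only for those.

An optional seeded broadband velocity perturbation (e.g. $10^{-2}$ relative)
can be added at excitation.  This matters because the band-edge mode of a
periodic chain and the symmetric top mode of a C3 trimer are *exact*
nonlinear solutions: they only decay through modulational instability, and
without an explicit perturbation that instability is seeded by round-off
noise, making onset times irreproducible.  The state is rescaled so the
total energy is still exactly $E_0$, and the seed is recorded.

## Breather detection

A discrete breather is localised and oscillates *above* the top of the
harmonic band, where it cannot resonate with any normal mode.  The detector
therefore compares the dominant peak of a probe displacement's power
spectrum with the harmonic band edge.  Spectra use a Hann window on the
mean-removed trace and quadratic interpolation of log-power around the grid
maximum, which recovers sub-bin peaks (a 300 ps window has 0.11 cm$^{-1}$
resolution); `is_breather` requires the gap to exceed the resolution.  The
probe is chosen operationally as the node with the highest time-averaged
energy over the analysis window.

Localisation is quantified by the participation ratio
$(\sum_i e_i)^2/(N\sum_i e_i^2)$ of node energies, in two flavours.  The
*time-averaged* distribution is the right measure when structural disorder
pins the breather (as in a protein, where it sits on specific residues).  In
a translationally invariant lattice the breather wanders, the time-mean
washes out to uniform by symmetry, and the mean *instantaneous*
participation ratio is the meaningful measure; both are reported.

Energy traces of a node group are Fourier-analysed with the mean removed,
reporting the dominant peak below 20 cm$^{-1}$ and above it separately (the
band division cleanly separates the slow energy-exchange oscillations from
the breather's energy oscillation, which sits at twice its displacement
frequency: the kinetic energy of a harmonic oscillation at $\omega$
oscillates at $2\omega$).

```{r trimer, eval = FALSE}
# the package's FMO-analogue demonstration (about 20 s)
tri <- make_c3_trimer(seed = 1)
net <- build_network(tri, r_c = 10, k2 = 10, k4 = 10)
modes <- normal_modes(net)
state <- excite(net, modes, mode_rank = 1, e0 = 60, perturbation = 0.02)
traj <- integrate_dynamics(net, state, n_steps = 3e5, stride = 200,
                           probe_nodes = 51)
ps <- power_spectrum(probe_trace(traj, 51), window = c(1e5, 3e5))
detect_breather(ps, modes, traj, window = c(1e5, 3e5), groups = "monomer")
```

## Vibronic spectra

The optical side treats a Frenkel exciton system — site energies
$\varepsilon_i$, couplings $J_{ij}$, transition dipoles $\boldsymbol\mu_i$
at positions $\mathbf r_i$ — with one discrete vibrational mode of frequency
$\omega$ coupled linearly to a chosen site subset:

$$H=\sum_i\varepsilon_i|i\rangle\langle i|+\sum_{i\ne j}J_{ij}|i\rangle\langle j|
 +\omega\,b^\dagger b+\sum_{i\in\mathcal C}g_i\,|i\rangle\langle i|(b^\dagger+b),
 \qquad g_i=\omega\sqrt{S_i}.$$

The $g_i=\omega\sqrt S$ convention reproduces the polaron (reorganisation)
shift $S\omega$ and the Poisson Franck–Condon progression
$e^{-S}S^n/n!$ exactly — both are asserted in the test suite against closed
forms.  Fifteen oscillator levels are kept by default; for $S\le 0.5$ the
spectra change by less than 0.1% between 15 and 25 levels.  The initial
vibrational state is the mode vacuum (no thermal population; at 77 K a
100 cm$^{-1}$ mode is ~15% populated, an approximation the user can probe by
lowering/raising $S$).

Transitions run from $|g, n{=}0\rangle$ to the one-exciton vibronic
eigenstates $\psi$ with amplitudes $c_{i\psi}=\langle\psi|i,0\rangle$:
linear absorption $|\boldsymbol\mu_\psi|^2$ with
$\boldsymbol\mu_\psi=\sum_i c_{i\psi}\boldsymbol\mu_i$; linear dichroism
$|\boldsymbol\mu_\psi|^2-3(\boldsymbol\mu_\psi\cdot\hat a)^2$ relative to the
supplied (C3) symmetry axis, the standard oriented-sample convention for
trimeric complexes; circular dichroism from the vibronic rotational strength
$R_\psi=\sum_{i<j}c_{i\psi}c_{j\psi}\,(\mathbf r_i-\mathbf r_j)\cdot
(\boldsymbol\mu_i\times\boldsymbol\mu_j)$.  An exact sum rule —
$\sum_\psi|\boldsymbol\mu_\psi|^2=\sum_i|\boldsymbol\mu_i|^2$ independent of
$S$, $J$ and disorder — is used as a standing correctness check.

Static disorder adds an independent Gaussian shift (FWHM 100 cm$^{-1}$ by
default) to every site energy in each of $n$ realisations (1000 by
default), re-diagonalises, dresses each stick with a Lorentzian of
configurable half-width (the Markovian lineshape), and averages.  Draws are
independent per site — including across symmetry-equivalent sites of
different monomers — and seeded.  One subtlety worth recording: disorder
leaves the spectral *first moment* at its clean value, and for a coupled
site that clean value is $\varepsilon_i$ itself (the intensity-weighted mean
of the Franck–Condon ladder), not the 0–0 line $\varepsilon_i-S\omega$.

Spectra are in arbitrary units with a peak-normalisation utility
(`normalise_spectra()`) that records its factors.  Site energies, couplings
and dipole geometries for real complexes are deliberately *not* bundled —
they are derived quantities from ab initio work and belong to the user; the
YAML exciton-config schema (`read_exciton_config()`) carries them.

## What the synthetic generators emulate — and what they don't

* `make_fpu_chain()` — a 1-D anharmonic lattice with an exactly known
  harmonic dispersion $\omega_q=\sqrt{4k_2/m}\,|\sin(qa/2)|$ (periodic
  boundaries use minimum-image distances, so the analytic band structure
  holds to machine precision).  It is the classical testbed for discrete
  breathers, but it is translationally invariant: breathers wander instead
  of pinning, and the 1-D topology has no geometric (bond-rotation)
  anharmonicity.  Its $k_4=0$ limit is *exactly* linear, which makes it the
  right fixture for the harmonic mode-purity check; a 3-D network with
  $k_4=0$ still carries weak geometric nonlinearity at finite amplitude.
* `make_c3_trimer()` — three seeded random blobs (20 nodes each, half-width
  7.5 Å, centred 10 Å off the axis) related by exact 120° rotations plus
  axial core nodes.  It reproduces the symmetry structure the analysis
  relies on (equal per-monomer shares of non-degenerate modes, C3-commuting
  Hessian) and the disorder needed to pin a breather, but it is not a
  protein fold: no secondary structure, no realistic degree distribution.
  Its demonstration excitation uses $E_0=60$ kcal/mol: the 63-node surrogate
  at the full trimer's canonical 40 kcal/mol would carry a ~20× higher
  per-node energy density, so the scale was set once to give clear
  localisation within a 300 ps window while staying in the stable-step
  regime, and not revisited.
* `make_vibronic_fixture()` — monomer/dimer/heptamer exciton systems whose
  spectra are known in closed form (FC progression, $2J$ splitting, dark
  states).  The heptamer mirrors the seven-pigment count of an FMO monomer
  but with random geometry.

Consequently, green tests demonstrate the *mechanisms* — band-edge
self-localisation above the phonon band, symmetry breaking, vibronic
sum rules — not quantitative agreement with any particular protein, which
requires the real structure and the user's exciton parameters.

## Numerical choices and edge cases

* Contact ties at exactly $R_c$ are excluded (strict inequality).
* Contact search is all-pairs $O(N^2)$ — exact by construction and cheap at
  $N\sim10^3$; it is tested against an independent brute-force oracle.
* Zero-mode threshold 0.1 cm$^{-1}$; eigenvector sign is not normalised
  (all derived quantities are sign-invariant; dynamics record the sign).
* Time-reversibility holds to $10^{-6}$ Å over $2\times10^4$ steps; over
  much longer horizons the chaotic dynamics amplifies round-off
  exponentially, which is a property of the system, not the integrator.
* Peak location uses log-power quadratic interpolation; comparisons of peak
  frequencies are made at ±0.5 cm$^{-1}$ or the spectral resolution,
  whichever is larger.
* Test and acceptance problem sizes: chains of 2–64 nodes, runs of 10 ps –
  1 ns, a 63-node trimer, vibronic systems of 1–7 sites × 15 levels, and
  400–1000 disorder realisations — all chosen so the full suite runs in a
  few minutes on one core while leaving every assertion far from its
  numerical floor.

## Known limitations

* No solvent friction or thermostat: the model targets the shielded core of
  a rigid complex; surface-damped modes are outside its scope.
* Which monomer the energy localises on depends sensitively on the
  excitation perturbation (a genuine instability of the symmetric state);
  analyses therefore use dominant-monomer *statistics*, never monomer
  identity.
* The Lorentzian linewidths are user inputs; no microscopic lineshape
  theory (beyond the Markovian limit it encodes) is implemented, and the
  optional low-frequency spectral peaks of energy traces are reported
  without a mechanistic assignment.
* No symmetry-adapted (irrep) mode classification; degenerate pairs are
  reported as the solver returns them.
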