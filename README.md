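# nnmodes

Anharmonic elastic-network analysis of protein vibrations — normal modes,
discrete breathers, and vibronic optical spectra — for pigment–protein
complexes such as the trimeric FMO (Fenna–Matthews–Olson) light-harvesting
complex, and for anyone studying nonlinear energy localisation in
coarse-grained biomolecular networks.

## The model

A structure is coarse-grained to point nodes (one 110 amu node per residue
at its C<sub>α</sub>; eight nodes per bacteriochlorophyll at the MG, C2A,
C2B, C2C, C2D, C2, C10, C18 atoms) and every node pair closer than a cutoff
*R<sub>c</sub>* interacts through the nonlinear network model (NNM) pair
potential

```
V = Σ_{i<j} c_ij [ (k2/2) (r_ij − R⁰_ij)² + (k4/4) (r_ij − R⁰_ij)⁴ ],
```

with contacts `c_ij` frozen at the input geometry (defaults R_c = 10 Å,
k2 = 10 kcal/mol/Å², k4 = 10 kcal/mol/Å⁴). The package:

* diagonalises the mass-weighted Hessian (normal modes in cm⁻¹, per-node
  amplitude shares, node-degree profiles);
* excites a chosen mode with total energy E₀ and integrates microcanonical
  velocity-Verlet dynamics at 1 fs, recording per-node energies;
* detects **discrete breathers** — localised oscillations whose frequency
  lies *above* the harmonic band edge — via Hann-windowed power spectra,
  energy Fourier peaks and participation ratios;
* computes disorder-averaged vibronic **LA / LD / CD spectra** for a Frenkel
  exciton system coupled to one discrete vibrational mode
  (`g = ω√S`, Lorentzian lineshapes, seeded Gaussian site-energy disorder);
* ships synthetic generators (anharmonic chains, C3-symmetric toy trimers,
  toy PDB files, analytic exciton fixtures) so the whole pipeline is
  testable offline.

## Worked example: symmetry breaking and a breather in a C3 trimer

```r
library(nnmodes)

tri   <- make_c3_trimer(seed = 1)                  # 63-node C3 surrogate
net   <- build_network(tri, r_c = 10, k2 = 10, k4 = 10)
modes <- normal_modes(net)
net
#> <elastic_network> 63 nodes (3-D), 426 contacts | k2 = 10, k4 = 10, r_c = 10
modes
#> <normal_mode_set> 189 modes (6 rigid-body) | band edge 125.175 cm^-1

# excite the top mode with 60 kcal/mol (plus a tiny seeded perturbation that
# triggers the modulational instability reproducibly) and run 300 ps
state <- excite(net, modes, mode_rank = 1, e0 = 60, perturbation = 0.02,
                seed = 1)
traj  <- integrate_dynamics(net, state, n_steps = 3e5, stride = 200,
                            probe_nodes = 51)      # 51 = hottest node
ps     <- power_spectrum(probe_trace(traj, 51), window = c(1e5, 3e5))
report <- detect_breather(ps, modes, traj, window = c(1e5, 3e5),
                          groups = "monomer", peak_band = c(50, 300))
report
#> <breather_report> main peak 134.628 cm^-1 | band edge 125.175 cm^-1 | gap 9.45 cm^-1 -> breather
#>   participation ratio 0.089 (~5.61 of 63 nodes) | dominant group M3 (63.2% of energy)
```

Reading this: the highest harmonic mode (125.2 cm⁻¹) is split equally across
the three monomers, but after excitation the anharmonic dynamics
spontaneously breaks the symmetry — 63% of the energy ends up on one monomer,
concentrated on ~6 of 63 nodes — and the oscillation now sits 9.5 cm⁻¹
*above* the top of the harmonic spectrum, the defining signature of a
discrete breather. The Fourier transform of that monomer's energy trace
shows the matching pair of peaks: a high-frequency peak at twice the
displacement frequency and a slow energy-exchange peak below 10 cm⁻¹.

For real structures, `read_pdb()` + `coarse_grain()` replace the generator
(the FMO crystal structure is PDB entry 3EOJ, user-supplied), and
`read_exciton_config()` loads user site energies/couplings for the spectra.
`run_pipeline()` (or `inst/scripts/nnm-pipeline.R` from a shell) chains all
stages from one YAML config with a seed-stamped manifest.

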