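---
title: "Surface-hopping dynamics of dioxetane thermolysis at desk scale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surface-hopping dynamics of dioxetane thermolysis at desk scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dioxhop)
```

## The problem

Thermolysis of *trans*-3,4-dimethyl-1,2-dioxetane (TDMD) is a
chemiluminescent reaction: after the O–O bond breaks, the biradical wanders
through a region where the four lowest singlet states and four lowest
triplet states are nearly degenerate (an *entropic trap*), hopping between
surfaces under weak spin–orbit coupling (SOC), until the C3–C4 bond finally
cleaves and the two acetaldehyde fragments depart on a definite electronic
surface. The fraction of trajectories ending on each product surface is the
chemiexcitation quantum yield; the time to C–C cleavage is the dissociation
time. Both are inherently dynamical quantities — they cannot be read off
stationary points of the potential-energy surfaces.

This package implements, at desk scale, the complete
simulation-and-analysis pipeline for that problem: a fewest-switches
surface-hopping (FSSH) engine with SOC operating in the diagonal
(spin-mixed) representation, driven on analytic model surfaces that stand
in for multireference ab initio surfaces, plus every statistic used to
interrogate the resulting ensemble. The ab initio electronic structure
itself (CASSCF energies, gradients and SOC matrix elements of the real
molecule) is out of scope by design; the analytic landscape reproduces the
*topological* features that control the dynamics, and the analysis layer is
verified against published worked-example arithmetic whose inputs are
printed tables.

## The model landscape

The configuration space is reduced to the coordinates the observables live
on: the C3–C4 distance $r$, the O1–O2–C3–C4 and C3–C4–C5–C6 dihedral
angles $\varphi_1, \varphi_2$, and $m = 3$ harmonic bath modes. The
electronic basis contains $n_S = 4$ singlets and $n_T = 4$ triplets with
their $S_z \in \{-1, 0, +1\}$ sublevels, $K = 16$ states of the molecular
Coulomb Hamiltonian (MCH) in total, ordered singlets first and triplets in
$S_z$-major blocks (the convention of SHARC-style intersystem-crossing
codes, and the column order of the transition-count matrices).

Every MCH potential shares a Morse well in $r$ (depth 1.0 eV, minimum at
1.60 Å) whose stiffness is set from the requested small-amplitude period of
40 fs — the C–C vibration that paces the frustrated dissociation attempts.
On top of that:

* **Excited-state ridges.** Every state except the ground singlet carries
  a Gaussian barrier (0.5 eV high, width 0.12 Å) centred at
  $r = 2.16$ Å, the crossing geometry at which dissociating trajectories
  top their active-state potential energy. A trajectory that leaves
  through an excited channel must pass over this ridge; the S0 channel has
  none — a grid scan of S0 between 2.1 and 2.4 Å contains no interior
  maximum, which the tests assert.
* **The entropic trap.** Outside a logistic window of $r$
  (1.35–2.20 Å, steepness 0.07 Å), states carry vertical offsets (up to
  1.2 eV); inside the window the offsets collapse to 5% of their value, so
  the sixteen diagonal energies at the launch geometry span less than the
  configured 0.2 eV trap width. T3 and T4 are pushed far above the active
  manifold (1.0 and 1.2 eV offsets): hopping into them is switched off in
  the engine, and their characters stay clear of the occupied states.
* **Sz sublevels.** Within each triplet the sublevels differ only by a
  $10^{-4}$ eV shift per $S_z$ unit, far below the 1 meV degeneracy bound
  asserted in the tests; hops among them continue even after dissociation,
  while the collapsed label stays frozen.
* **SOC.** Constant matrix elements — 10 meV between singlets and triplet
  sublevels of different $S_z$ (imaginary), 2 meV between triplet
  sublevels (real) — damped logistically to zero beyond $r = 3.0$ Å, so
  the separated fragments decouple. No magnitudes for TDMD are published;
  these are order-of-magnitude choices and fully configurable.
* **NAC.** Derivative couplings between adjacent states of equal
  multiplicity and $S_z$ point along $r$ with a Gaussian magnitude centred
  at the ridge (width 0.3 Å), mimicking localized crossing regions.
* **Mode coupling (IVR).** A saturating function of C–C elongation
  multiplies torsional cosines (0.12 eV) and linear bath displacements
  (1.2 eV). This term matters: without it the reduced model is separable,
  energy placed in the torsions and bath at launch can never reach the C–C
  stretch, and almost every trajectory stays trapped forever. With it the
  trap region is chaotic, energy redistributes on a ~100 fs scale, and the
  ensemble reproduces the qualitative regime of the full-dimensional
  study: a minority of ballistic early dissociations, a long tail of
  trajectories delayed by tens of frustrated dissociations, and a few
  percent that outlive the time budget. The bath coupling acts only
  through bath displacements, so it cannot create spurious structure in
  the fixed-coordinate ridge scans; the torsional strength is kept small
  enough that the S0 channel stays barrierless for any fixed angles.

Units are eV, Å, fs, amu throughout, with angles in degrees at every
user-facing boundary; the two conversion constants
(1 amu Å²/fs² = 103.6427 eV and $\hbar$ = 0.6582120 eV fs) live in a single
exported list, `dioxhop_constants`.

## The engine

`run_trajectory()` couples four pieces per 0.5 fs step:

1. **Nuclei** move by velocity-Verlet on the active *diagonal* surface —
   an eigenvalue of $H^\mathrm{total} = H^\mathrm{MCH} + H^\mathrm{SOC}$ —
   with gradients from central differences (step $10^{-4}$) on the
   eigenvalues, since the surfaces are analytic in the MCH basis but not in
   the diagonal one.
2. **Frames** at successive geometries are aligned by greedy
   overlap matching with deterministic phase fixing, preventing spurious
   state relabeling through trivial crossings; the Löwdin-orthonormalized
   overlap supplies the time-derivative coupling
   $T \approx (S - S^\dagger)/2\Delta t$, to which the transformed
   $\mathbf{v}\cdot\mathbf{d}$ NAC matrix is added.
3. **Electronic coefficients** evolve under the Hermitian effective
   Hamiltonian $H(\tau) = \mathrm{diag}(E(\tau)) - i\hbar T$ interpolated
   across the step, by sub-stepped unitary exponentials (25 substeps). A
   constant Hamiltonian is propagated exactly through one
   eigendecomposition; the engine's case — constant off-diagonal block —
   uses Strang splitting with a precomputed coupling exponential; the
   general case exponentiates midpoint Hamiltonians. Every path is exactly
   unitary, and the tests hold the norm to $10^{-8}$ over $10^4$ steps and
   the two-state Rabi problem to $10^{-6}$ of the closed form.
4. **Hops** follow Tully's fewest-switches prescription on the population
   flux out of the active state, with targets whose dominant character is
   T3/T4 masked to zero. An accepted hop rescales the velocity component
   along the NAC direction between the states' dominant characters
   (falling back to the full velocity vector when that direction
   vanishes, e.g. across a spin flip) so total energy is conserved to
   machine precision; insufficient directed kinetic energy frustrates the
   hop, which is recorded and, by default, leaves the velocities
   untouched (reversal is available by flag). Energy-based decoherence
   then damps every non-active amplitude with
   $\tau_k = \hbar/|E_k - E_a| \,(1 + C/E_\mathrm{kin})$, $C$ = 0.1 hartree.

A trajectory records every step; its dissociation time is the first sample
with $r > 2.4$ Å (strictly greater, no interpolation — which is why
half-femtosecond-quantized times and quarter-femtosecond medians arise),
the product label is the dominant MCH character at that sample with
$S_z$ collapsed, and the run ends at $r > 3.7$ Å, at `t_max`, or when
total energy drifts by more than 0.2 eV (status `failed_energy`, the
analogue of the small fraction of failed ab initio trajectories). A change
of the collapsed label after cleavage is tracked as `label_drift` and
asserted absent in the tests rather than enforced, since only $S_z$ hops
should survive the lifted degeneracy.

## Initial conditions

All trajectories launch from the same geometry — the surrogate of the O–O
bond-breaking transition state, with the O1–O2–C3–C4 dihedral at its
135.8° value — with velocities Boltzmann-sampled at 300 K, globally
rescaled to exactly 3.96 eV of kinetic energy, and forward-selected along
the reaction mode. The 3.96 eV figure (zero-point energy plus a
perturbative correction in the original workflow) is treated as a plain
configuration input. Backward samples have their reaction-mode component
reflected in mass-weighted velocity space, which preserves kinetic energy,
all orthogonal components and the forward marginal; rejection sampling is
available by flag. The reaction mode is taken along the C–C stretch: in
the reduced space it is the coordinate that carries the trajectory toward
products, and the O–O and C5–C6 stretch rates are represented by bath-mode
surrogates in the feature set (`v0_12`, `v0_56`) used for the
endpoint-subrange classification.

## The analysis layer

Each operation is the literal counterpart of a published definition, and
each is tested against an independent oracle or printed arithmetic:

* **Transition-count matrices** tabulate step-to-step MCH transitions
  (diagonal: within-state steps; off-diagonal: hops). **Residence times**
  are the diagonal element plus the off-diagonal *column* sum — the
  destination convention, under which the first sample is attributed to no
  state — times 0.5 fs. Applied to the shipped worked-example matrices
  this yields 30.5 / 5.5 / 34.0 / 9.5 fs (total 79.5 fs) for the short
  trajectory and 546.0 fs in T1 for the long one, exactly.
* **Frustrated dissociations** are interior strict local maxima of the
  C–C series up to the final crossing of 2.4 Å, with a 0.05 Å topographic
  prominence filter to suppress integrator jitter (the published counts
  were visual; the acceptance series are analytically clean, so the filter
  is irrelevant there). A ~40 fs oscillation over 975.5 fs yields 24 peaks
  and a 40.6 fs mean period.
* **Dihedral unwrapping** lifts wrapped angles (−180°, 180°], where −180°
  equals +180°, to a continuous path; the worked waypoint sequence
  135.8 → 180(−180) → −90 → 0 → 32.9 unwraps to a 257.1° variation.
* **Quantum yields** are percentages of completed trajectories;
  **half-times** are sample medians with the midpoint convention for even
  counts (the only definition consistent with printed quarter-femtosecond
  values such as 253.25 fs).
* **Population time series** freeze each terminated trajectory at its
  product label (collapsed for triplets; the last $S_z$ sublevel in the
  full-MCH basis; the last index in the diagonal basis). The published
  population panels extend beyond individual trajectory lifetimes without
  stating a convention; freezing is the choice that makes the final
  collapsed populations equal the quantum yields exactly, which the tests
  assert. `detect_equilibrium()` requires the settled stretch to exceed a
  caller-chosen window, so indefinitely fluctuating $S_z$-sublevel
  populations correctly report "never".
* **RLSE** (relative length of the subrange near an endpoint) quantifies
  how strongly extreme initial velocities predispose a product state:
  the distance from a global feature-range endpoint to a state's nearest
  value on that side, as a percentage of the range length. Computed from
  the printed ranges it reproduces 20.0 / 25.0 / 12.5 / 23.1 / 33.3%.

## What the synthetic ensemble does and does not show

The generator emulates the *conditions* of the study — the launch
protocol, the 0.5 fs / 2.4 Å / 3.7 Å engine constants, the trap topology,
the ~40 fs C–C clock — but its surfaces are analytic stand-ins, not fits
to CASSCF data. Ensemble-level numbers that depend on the real
high-dimensional landscape (the 23.2 / 59.6 / 17.2% yields, the 178 fs
half-time, the 4200 fs equilibrium point) are therefore *not* targets for
the surrogate; they are verified as pure arithmetic on the printed tables
instead. What the surrogate ensemble is held to are the structural
invariants: unit norm, energy conservation across hops, zero triplet yield
at zero SOC, determinism under the master seed, yield normalization,
agreement of disjoint half-ensembles at the 95% level (by exact test,
appropriate for desk-scale counts), and product labels confined to the
non-masked manifold.

Problem sizes were chosen for a desk machine: the packaged study run
(`analysis/01_simulate.R`) uses 310 trajectories of up to 2000 fs on the
full 16-state model, while the test suite exercises ensembles of 30
trajectories of 250 fs on a reduced 8-state model (2 singlets + 2
triplets, one bath mode), which visits every code path at a fraction of
the cost.

## Numerical choices and degenerate inputs

* Eigenvalues are returned ascending with eigenvector phases fixed by
  making the largest-magnitude component real positive; ties in the MCH
  character assignment resolve to the first (lowest-ordered) label.
* The hop momentum-adjustment quadratic takes the root of smaller
  magnitude (the gentler velocity change); a zero discriminant is an
  accepted grazing hop.
* `rescale_to_energy` refuses all-zero velocities; `select_forward`
  signals a redraw on a numerically zero projection rather than guessing
  a direction.
* Zero kinetic energy disables decoherence damping (infinite
  $\tau$), as do states degenerate with the active one.
* Configuration files round-trip through YAML, unknown keys are rejected
  by name, and every invalid physical parameter names its field.

## Known limitations

The surrogate's product-state branching is sensitive to the (unpublished)
SOC magnitudes and to the trap's residual splittings, so its yields should
be read as regime-level, not quantitative, statements about TDMD. The
gradient of the active diagonal surface costs $2d$ eigenvalue solves per
step; a Hellmann–Feynman path would be faster but was deliberately not
used, keeping the engine agnostic to how the model potentials are
supplied. Wavepacket effects, tunnelling through the ridges, and
surface-hopping variants beyond FSSH with energy-based decoherence are out
of scope, as is any fit of the analytic landscape to ab initio data.
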