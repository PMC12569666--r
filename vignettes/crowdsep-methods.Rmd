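---
title: "Models and methods behind crowdsep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind crowdsep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(crowdsep)
```

This vignette is the package's own account of its science: the
coarse-grained model, the sampling machinery, the observables, the
synthetic fixtures that validate them, and the numerical choices made
where the design was genuinely open.

## 1. The coarse-grained model

### Protein

Each residue is one bead on a harmonic backbone. Three energy terms act
between beads:

* **Bonds** between consecutive residues, `k_b (r - r_0)^2` with
  `k_b = 1000` kcal/(mol nm²) and `r_0 = 0.382` nm. The spring constant
  follows the convention *without* the ½ factor; anyone porting parameters
  from a force field using `½ k (r-r0)²` must double their constant.
* **Hydropathy-scaled van der Waals** interactions in the Ashbaugh–Hatch
  form. Below the Lennard-Jones minimum `2^{1/6} σ_ij` the potential is
  the full LJ plus `(1 - λ_ij) ε`, so the repulsive core is independent of
  hydropathy and the two branches meet continuously at `-λ_ij ε`; above
  it, the attractive tail is scaled by `λ_ij`. Pair coefficients follow
  `σ_ij = (σ_i + σ_j)/2` and `λ_ij = μ (λ⁰_i + λ⁰_j)/2 - Δ` with `μ = 1`,
  `Δ = 0.08`. The arithmetic-mean-then-affine-map order is the standard
  HPS convention; combined λ may be slightly negative (e.g. two
  glutamates) and is used as-is, giving a weakly repulsive tail.
* **Debye–Hückel electrostatics**,
  `k_e q_i q_j e^{-κr} / (ε_r r)`, with `ε_r = 80`, `κ = 1` nm⁻¹
  (≈100 mM monovalent salt at 300 K). Charges follow the fixed pH-7 rule:
  arginine and lysine +e, aspartate and glutamate −e, histidine and all
  others neutral. The table constructor enforces this rule, because a
  silently flipped charge is the hardest parameter bug to find.

The per-residue table (mass, σ, λ⁰, charge) is a *pluggable input* shipped
as an editable TSV (`extdata/hps_urry_params.tsv`, the standard published
HPS-Urry set). The test suite deliberately uses small synthetic tables so
that no test depends on literature parameter values.

### Crowders

Crowders are single spherical beads (mass 1500 amu, radius `r_c = 0.8` nm)
emulating PEG1500-like agents. Protein–crowder and crowder–crowder
interactions use shifted inverse-power kernels in the reduced coordinate
`x = (r - Δ)/σ_ref`, `σ_ref = 0.6` nm:

* protein–crowder, repulsive mode: `4 ε x^{-12}`;
* protein–crowder, attractive mode: `4 ε (x^{-12} - x^{-6})`;
* crowder–crowder, always repulsive: `4 ε x^{-12}` with its own shift.

The shifts are *derived*, never set by hand:
`Δ_pc = r_0/2 + r_c − σ_ref = 0.391` nm and
`Δ_cc = 2 r_c − σ_ref = 1.0` nm. A printed form of the kernel could also
be parsed as `(σ_ref/r − Δ)^{12}`; we implement the shifted-distance
reading `(σ_ref/(r − Δ))^{12}`, which is the one consistent with the
stated size-shift semantics and with the companion crowding literature.
The alternative parse has no finite minimum at a sensible contact
distance. The two kernels live in one pair of internal functions
(`.shifted_rep` / `.shifted_lj`), so swapping the functional form is a
two-line change.

The crowder count realising a volume fraction C inverts
`C = N (4/3)π r_c³ / V` under the **floor** convention. Floor reproduces
all twelve published counts for the 25 nm cube and the 12.5 nm sphere and
the 5%/20%/25% slab counts; the published slab counts at 10%, 15% and 30%
are one higher (rounding-to-nearest), so no single convention reproduces
every printed value — the slab box is also described as only
"approximately" 15 nm wide. We adopt floor because eleven of fourteen
independent counts pin it and it guarantees the realised fraction never
exceeds the request.

### Truncation and exclusions

All nonbonded terms are plainly truncated at 3.5 nm — no tail corrections,
no shifting. At `ε = 0.2` kcal/mol the vdW energy at 3.5 nm is below
3×10⁻⁵ kcal/mol, so the discontinuity is negligible against thermal
noise. Only directly bonded `(i, i+1)` pairs are excluded from nonbonded
terms (1–3 pairs interact, the usual HPS convention), plus all pairs
inside the same rigid segment, whose geometry is fixed anyway.

## 2. Sampling

### Langevin dynamics

The integrator is BAOAB splitting of underdamped Langevin dynamics. The
damping parameter follows the LAMMPS time-constant convention: friction
force `−(m/damp) v`, so every bead's velocity relaxes on the same time
`damp` regardless of mass, and the free-particle diffusion coefficient is
`D = k_B T · damp / m`. Defaults mirror the slab protocol (10 fs
timestep, damp = 1000 ps for phase coexistence, 1 ps for
replica-exchange-style runs, frames every 100 ps). BAOAB was chosen over
other splittings for its configurational accuracy at large timesteps —
the bonded dimer sampled at 300 K reproduces the analytic bond-length
density `p(r) ∝ r² exp(−k_b(r−r_0)²/k_BT)` with a Kolmogorov–Smirnov
distance of ~0.003 at 10⁵ samples.

Units are nm / ps / amu / kcal/mol with
`k_B = 0.0019872041 kcal/(mol K)`; in this system
1 amu nm²/ps² = 1 kJ/mol, so the only conversion constant in the
integrator is the factor 4.184 between force and acceleration.

### Rigid segments

The α-helical segment is held internally rigid. Rigid ranges become rigid
*bodies*: bead coordinates are stored once in the body's principal frame
and world positions are always regenerated as `com + R · body_coords`, so
intra-segment distances are preserved exactly by construction (observed
deviation ~10⁻¹⁵ relative). Translation uses the summed force on the
body; rotation integrates the world-frame angular velocity from the
summed torque with the principal inertia tensor, with the thermostat
applied per principal axis. Degenerate (near-collinear) bodies zero the
singular axis. Reference helix coordinates are not prescribed; any ideal
helix template works, and the slab builder uses the chain geometry it
packed.

### NVE validation

`run_nve()` (velocity Verlet, no thermostat) exists to certify force
correctness: a bonded dimer shows a secular energy drift below 10⁻⁴
relative over 10⁵ steps and matches the analytic oscillator period
`2π√(m_red/2k_b)` to 10⁻⁵, and total linear momentum is conserved to
machine precision. The drift statistic is the fitted linear slope times
the run length over the mean energy — the symplectic fluctuation band is
not drift.

### Slab construction

The published protocol compresses a random chain packing with a brief
100 atm NPT run and then elongates the box. A barostat is sampling
machinery, not an observable, so compression is implemented as stepwise
isotropic affine rescaling (factor 0.95 per cycle) interleaved with short
strongly-damped Langevin relaxations until the target cube is reached;
the end state — a dense protein cube — is what matters. Elongating the
box along z keeps all coordinates (minimum-image distances of interior
beads are unchanged, which the tests verify as a geometric identity) and
crowders are then scattered uniformly through the elongated box outside
the singular shifts.

### Temperature ladder

`ladder_exchange()` implements neighbour-pair Metropolis swaps with
acceptance `min(1, exp[(β_i − β_j)(U_i − U_j)])`, alternating even/odd
pairings between sweeps, exchanging configurations and rescaling
velocities by `sqrt(T_new/T_old)`. The production-scale ladder (32
replicas, 150–800 K, 10 μs each) is accepted by the configuration
objects but is cluster-scale; desk use is a handful of replicas over a
narrow band.

## 3. Observables

All time-averaged observables share one equilibration contract: frames
with `time >= t_init` enter the average, and changing `t_init` changes
*only* the frame selection, never the estimator (tested by recomputing on
a manually truncated trajectory).

* **Density profile**: per-frame recentring puts the protein z-centre of
  mass at Lz/2 before histogramming. The centre is a *circular* mean
  (z mapped to an angle), so condensates spanning the periodic boundary
  recentre correctly — an ordinary mean splits them into two half-slabs.
  ρ_h is the mean protein density over a central window (half-width
  defaulting to Lz/4, configurable; the quantity is defined on the figure
  level in the source work, so the window is an explicit knob). The
  surface band is the z-interval where density crosses 0.2–0.8 of the
  maximum, located by linear interpolation between bins scanning outward
  from the centre.
* **Crowder RDF**: shell counts about the protein centre of mass,
  normalised by `4πr²Δr` at bin centres, `Δr = 0.1` nm.
* **Internal/external crowders**: internal means inside the mean Rg of
  the protein; external means in a proximity shell just outside it. The
  shell width is a documented free parameter (default 1 nm) — the source
  figures define the category only qualitatively.
* **MSD and diffusion**: the z-displacement of each chain's unwrapped
  centre of mass, time-averaged over all sliding origins, then averaged
  over chains; `fit_diffusion()` fits `log MSD = α log Δt + log 2D`. An
  optional log-spaced lag subsample keeps the dense, strongly correlated
  long lags from dominating the least-squares line — with uniform lag
  weighting a single 10⁴-step Brownian path yields α anywhere in
  [0.82, 1.18] across seeds, with log spacing and a small chain ensemble
  the spread tightens to [0.96, 1.04].
* **Contact maps**: indicator of `r < 0.75(σ_i + σ_j)`, time-averaged.
  Intra-chain maps exclude `|i−j| < 3` by default (bonded and
  next-nearest neighbours are always in contact and would saturate the
  diagonal). Inter-chain maps average over all ordered chain pairs, which
  makes them symmetric.
* **Region contact numbers**: block means of the inter-chain matrix over
  region ranges I×J. I = J (Helix–Helix) is supported: the "different
  segments" phrasing in the defining equation is read as describing the
  cross-region listing, since the headline results themselves include
  same-region pairs.
* **Contact relaxation**: per chain-pair region-contact series, ACFs
  (mean-subtracted, normalised, via `stats::acf`) averaged across pairs
  *before* fitting — pooling is declared in the output. τ comes from a
  least-squares line through `log L` over the contiguous window from lag
  zero where L exceeds a floor (default 0.05). If the window collapses
  (white-noise-like series) τ is read off the first lag, giving a value
  below one frame interval, and an all-non-positive ACF is an error.
* **Segment orientation**: a representative vector from random residue
  draws — base point from the second half and tip from the first half for
  Helix/IDR1-sense segments, the reverse for IDR2 — then
  `φ = arccos(r·ẑ/|r|)` in degrees. Raw φ values are histogrammed (no
  sin φ solid-angle weighting): the defining relation is used as written,
  so an isotropic ensemble shows the sin φ envelope in the histogram
  itself, which is exactly what the validation test asserts. Orientation
  maps recentre z identically to the density profile and split
  surface-restricted distributions by left/right interface.

## 4. Synthetic fixtures and what passing means

The generators emulate *statistical structure*, not force-field physics:
Brownian paths (exact Gaussian increments), Ornstein–Uhlenbeck series
(exact discretisation, ACF `e^{-Δt/τ}`), tanh-interface slabs (plateau
density solved exactly by adjusting the half-thickness; 0.2/0.8 crossings
at `z₀ ± w·atanh 0.6`), ideal gases, two-chain contact toys with
scheduled contacts, and orientation fans with prescribed angles. Each
emits a machine-readable key consumed by the tests.

Passing these tests certifies the estimators — not the realism of any
simulated condensate. Real slab trajectories add correlated frames,
finite-size interface fluctuations and chain connectivity that the
fixtures deliberately omit; conclusions about real systems still require
converged sampling at production scale (100 chains × 5 μs in the source
protocol, versus the 2–10 chains × tens of ns exercised here). Problem
sizes in the suite (10⁴–10⁵ samples, ≤100-bead oracle systems,
10⁵-step conservation runs) were chosen as the smallest at which each
stated tolerance is comfortably resolved.

## 5. Numerical choices and degenerate inputs

* Positions are N×3 matrices; user-facing residue numbering is 1-based
  inclusive (with full-protein numbering 267–414 carried alongside local
  indices for the CTD regions).
* Pair enumeration is a precomputed i<j list; at desk scale (≤~2500
  beads) a full pair list beats cell lists in R, and the evaluator equals
  a naive double-loop oracle on randomized systems.
* Singular shifted kernels (r ≤ Δ) abort with the offending pair named;
  the slab builder and fixtures place beads outside the singular region
  by construction.
* Integration blow-ups (non-finite coordinates) abort with the step
  index.
* Degenerate orientation vectors (coincident residues) are resampled a
  bounded number of times, then error.
* Determinism: every stochastic entry point takes a seed; identical seed
  and configuration give bitwise-identical trajectories on one platform.

## 6. Known limitations

* No barostat: compression is scripted rescaling; anisotropic pressure
  control and surface-tension routes to coexistence are out of scope.
* No Ewald electrostatics, solvent, angular/torsional terms, or enhanced
  sampling beyond the temperature ladder.
* Pure-R kernels: production-scale runs (hundreds of chains,
  microseconds) belong to dedicated MD engines; the topology and pair
  tables export to LAMMPS formats for exactly that hand-off.
* The repulsive-versus-attractive dense-phase-density ordering at high
  crowding is a long-running qualitative study
  (`scripts/crowding_comparison.R`), not a unit test: at desk scale the
  effect is within interface fluctuations unless run for hours.
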