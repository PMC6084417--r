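---
title: "Models and methods behind smalpr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind smalpr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smalpr)
```

# The system

Styrene–maleic acid (SMA) copolymers solubilize lipid membranes into
nanometer-sized bilayer disks (SMA lipid particles, SMALPs) whose
hydrophobic rim is wrapped by the polymer. `smalpr` implements the
modelling side of that story at Martini-style coarse-grained (CG)
resolution: building the CG polymer topology, deriving its bonded
parameters from atomistic reference data, and quantifying the
membrane-disruption observables — pores, nanodisks, radius of gyration,
density profiles, flip-flop — on CG trajectories. Full nonbonded CG
molecular dynamics is deliberately out of scope; the sampling component
covers only the single-molecule bonded ensemble that the parameter
refinement loop needs.

# The CG SMA model

One repeat unit is styrene–styrene–maleic acid (a 2:1 composition). Each
styrene maps to one backbone bead plus a three-bead aromatic ring; because
ring bond-length fluctuations are tiny at CG resolution, the ring edges are
*constraints* (fixed lengths) rather than stiff bonds, which would demand a
very small integration/sampling step. The maleic acid maps to two one-bead
carboxylate groups. A fully deprotonated unit carries −1 e on each
carboxylate, −2 e per unit; the default 23-unit chain therefore carries
−46 e and weighs

$$
M = 23\,(2 M_{\mathrm{C_8H_8}} + M_{\mathrm{C_4H_4O_4}}) - 46\,M_\mathrm{H}
  \approx 7.41\ \mathrm{kDa},
$$

the ~7.4 kDa chain used throughout. The "50 % charged" preset protonates
every second unit, so the 23-unit chain keeps 12 charged units (−24 e).
Masses follow the Martini convention: 72 Da regular beads, 45 Da small ring
beads. Bead *type codes* (`SC1`, `SC4`, `Qa`, `P3`) are labels for the
emitted ITP file only; nothing numeric depends on them. The exact bead
identities of the published model are not enumerable from text sources, so
the per-unit layout lives in a configurable table (`sma_defaults()`) whose
default — 2 × (backbone + 3-bead ring) + 2 carboxylates = 10 beads/unit —
mirrors published Martini styrene and phenylalanine practice. Whether the
maleic backbone carbons belong to the carboxylate beads was genuinely open;
the default absorbs them, which keeps the unit at ten beads and the
backbone four beads long per unit.

Bonded interactions use the GROMACS functional forms implied by the model
class: harmonic bonds $\tfrac12 k_b (b-b_0)^2$ and harmonic improper
dihedrals $\tfrac12 k_\xi(\xi-\xi_0)^2$; cosine-harmonic (G96) angles
$\tfrac12 k_a(\cos\theta-\cos\theta_0)^2$; periodic proper dihedrals
$k_\phi(1+\cos(n\phi-\phi_s))$; and a flat-bottomed distance restraint that
is zero inside its onset $d_0$ and harmonic beyond it. The restraint
default $d_0 = 3.0$ nm reproduces the adsorption restraint used to keep
copolymers near the membrane before binding; its force constant is not
stated anywhere we could find, so the default is 1000 kJ mol⁻¹ nm⁻²,
configurable.

# From atomistic data to CG parameters

`map_frame()` converts an atomistic trajectory to a *pseudo-CG* trajectory:
each bead sits at the mass-weighted centroid of its atoms
(center-of-mass mapping, the standard Martini choice; geometric-center
mapping is obtained by passing unit weights), with each bead group
unwrapped by minimum image before averaging so periodic wrapping cannot
shear a bead apart. Hydrogens participate with their masses unless the
scheme excludes them.

`compute_distribution()` histograms bonds (0.001 nm bins), angles (1°) and
dihedrals (2°, support (−180°, 180°]) into densities normalized so that
$\sum_i p_i \Delta_i = 1$. Distributions are compared with the
Jensen–Shannon divergence in base 2 — bounded in [0, 1], symmetric,
zero iff equal, one for disjoint supports — because the match metric used
originally is unspecified ("best match"); the overlap coefficient is also
available (`distribution_overlap()`).

**Direct Boltzmann inversion** (`boltzmann_invert()`) turns a target
distribution into initial parameters: $b_0 = \langle b\rangle$,
$k_b = k_BT/\mathrm{var}(b)$ for bonds; $\cos\theta_0 = \langle
\cos\theta\rangle$, $k_a = k_BT/\mathrm{var}(\cos\theta)$ for angles (the
G96 form acts on $\cos\theta$, whose sampling measure is flat, so no
Jacobian correction is needed); a weighted least-squares fit of
$k_\phi(1+\cos(n\phi-\phi_s))$ to $-k_BT\ln p(\phi)$ over candidate
multiplicities $n \in \{1,2,3\}$ for proper dihedrals. A bond distribution
with a standard deviation below 0.005 nm is promoted to a constraint at its
mean — the same decision that makes the aromatic rings constrained — and a
multimodal bond distribution is refused, since a single harmonic term
cannot represent it.

**Iterative refinement** (`refine_parameters()`) alternates sampling the
current model with moment-matching updates until the largest per-term JSD
drops below `tol` (default 0.02) or `max_iters` (default 20) is reached,
always returning the best model seen. The update scheme is the package's
own design (the original work reports only "a couple of iterative steps"):

* bonds: $b_0 \mathrel{+}= \langle b\rangle_{tgt} - \langle b\rangle_{sim}$,
  $k_b \mathrel{*}= \mathrm{var}_{sim}/\mathrm{var}_{tgt}$;
* angles: the same on $\cos\theta$, but through *truncation-corrected*
  moments: the sampled $u=\cos\theta$ follows a Gaussian truncated to
  $[-1,1]$, and for wide or near-linear angles the raw variance
  systematically underestimates $k_BT/k_a$. We invert the truncated-normal
  moment formulas (fixed-point iteration) on both target and simulated
  histograms before matching; without this the recovered $k_a$ of wide
  angles is biased low by up to ~15 %;
* proper dihedrals: $k_\phi$ is rescaled by the ratio of well depths, with
  the depth measured as the fitted cosine amplitude of the inverted
  potential rather than its raw max–min, which is dominated by the noise
  of rarely visited bins;
* improper dihedrals: circular-mean shift and variance matching in $\xi$.

If the metric rises three iterations in a row the update step is halved
once; if it keeps rising the fit stops with `converged = FALSE`.

# The bonded-ensemble sampler

Only *equilibrium* bonded distributions are needed by the loop, so the
in-package simulation is Metropolis Monte Carlo rather than Langevin or MD —
no integrator, thermostat or nonbonded machinery. Moves are (i) single-bead
displacements (uniform in a cube, default half-width 0.06 nm), (ii) rigid
translation+rotation of constraint-closed ring triplets, which keeps
constraint lengths exact to machine precision by construction, and (iii)
pivot moves — rotation of everything on one side of a severable bond about
that bond's axis — which decorrelate torsions and angles orders of magnitude
faster than local moves alone (30 % of moves by default). The hot loop is
C++ (via Rcpp) with per-move incidence lists so each move costs only its
incident terms; $k_B = 0.0083145$ kJ mol⁻¹ K⁻¹ and the default temperature
is 310 K, the temperature of the membrane simulations being emulated.

Correctness anchors: for a single harmonic bond the sampled variance must
approach $k_BT/k_b$ (equipartition; the $b^2$ Jacobian shifts it by
$\sim 2\sigma^2/b_0^2$, which the test tolerances accommodate), and the
independent `sample_reference_ensemble()` generator — inverse-CDF and
rejection draws straight from the Boltzmann densities, no Markov chain —
provides cross-checks and analytic target histograms for the recovery
tests.

# Membrane observables

All analyses run on tibble-based frames (`cg_frame`) in nm with
orthorhombic boxes, the bilayer normal along z by convention.

* **Radius of gyration**: mass-weighted, after sequential minimum-image
  unwrapping so chains crossing the boundary reassemble. Verified against
  the pairwise identity $R_g^2 = \sum_{ij} m_i m_j r_{ij}^2 / 2M^2$.
* **Density profiles / ion asymmetry**: time-averaged number densities in
  slabs; asymmetry $=(N_\uparrow - N_\downarrow)/(N_\uparrow+N_\downarrow)$
  about the bilayer midplane (median tail-bead z by default), the statistic
  behind the observation that sodium distributes asymmetrically around a
  polymer-loaded membrane.
* **Leaflets and flip-flop**: leaflet = sign of head z minus midplane; a
  flip-flop is a label change persisting at least `dwell` frames
  (default 5), which suppresses boundary flicker.
* **Pore detection**: tail beads within 0.8 nm of the midplane are
  rasterised on a 0.3 nm xy grid; a cell is occupied within 0.264 nm (the
  CG bead radius) of a bead, a one-cell morphological closing fills the
  packing corridors between lipids, and pores are periodic-wrap-aware
  4-connected components of the remaining empty cells above 0.5 nm².
  Area = cell count × cell area; the equivalent diameter $2\sqrt{A/\pi}$,
  radius and area are all reported, since the original size metric is not
  specified. On planted circular pores of radius 1–5 nm the recovered
  diameter is within two grid cells (0.6 nm) of truth; the absolute area
  of a lattice-planted pore is only defined to about one lipid footprint
  (~0.63 nm²), which is the natural resolution of that fixture. Tracking
  across frames is greedy nearest-centroid matching, largest pores first.
* **Aggregates and nanodisks**: single-linkage clustering under a
  minimum-image cutoff (cell lists + igraph components; labels are
  canonicalised by size then smallest molid, so the partition is invariant
  under particle re-ordering). A disk is characterized by a principal-axes
  plane fit of the per-lipid centroids; diameter = equivalent circle of the
  convex hull of all projected lipid beads (the convention is stamped on
  the record; $2\sqrt{2}\,R_{g,2D}$ is the common alternative); planarity =
  RMS deviation of the terminal tail beads (the bilayer midsurface) from
  the plane; a polymer chain belongs to a disk when at least half its beads
  lie within 1 nm of a lipid bead.
* **Extracted lipids**: all tail beads outside the membrane slab *and*
  within 0.6 nm of a polymer bead.

# Synthetic fixtures and what passing them means

`make_bilayer()` builds lattice bilayers (26 × 26 × 2 = 1352 lipids matches
the reference system size) with an 8-bead DDPC-like template; tail length is
configurable for DMPC/DPPC analogues. `punch_pore()` removes lipids inside
a circle (optionally tilting rim heads inward to emulate a toroidal pore)
and records the removed molecules as ground truth. `make_nanodisk()` lays
lipids on concentric rings whose outermost ring sits exactly at the nominal
radius $\sqrt{n_{leaflet}\,\mathrm{APL}/\pi}$ — chosen over a sunflower
spiral because it keeps the disk edge populated, so the convex-hull
diameter of a planted disk tracks the geometric value within a few percent
down to 50 lipids. The planted 150-lipid disk at 0.63 nm²/lipid has
geometric diameter 7.76 nm, inside the reported 7–9 nm range for
self-assembled disks at the 150:1 lipid/polymer ratio.

These fixtures are idealised: lattices have no thermal disorder, planted
pores are perfect circles, disks are flat. Passing the suites shows the
*operations* are correct (geometry, accounting, periodic wrap, tracking),
not that the physics of a real CG trajectory is reproduced — the latter
requires the out-of-scope MD engine.

# Numerical choices and problem sizes

Defaults: APL 0.63 nm², bilayer thickness 2.4 nm (short-tail DDPC), grid
cell 0.3 nm, slab half-width 0.8 nm, aggregate cutoff 0.6 nm, JSD tolerance
0.02, $k_B T$ at 310 K = 2.577 kJ mol⁻¹. The recovery test suite samples
4–6 × 10⁵ Monte Carlo moves per iteration on 4-bead chains and converges in
one or two refinement iterations per parameter set; the bundled checks use
20 randomized parameter sets with force constants perturbed ±30 %, and
recover them within 10 % (equilibria within 2 %). Angle force constants are
drawn from 35–85 kJ mol⁻¹ at equilibrium angles of 105–135°, the regime of
CG polymer models; far outside it (near-linear angles with weak constants)
the $\cos\theta$ truncation dominates the distribution and a harmonic
description itself stops being meaningful.

# Known limitations

No nonbonded terms, solvent, or multi-molecule dynamics: the sampler
cannot fold a chain onto a membrane. Orthorhombic boxes only. The ITP
dialect covers the sections this model family uses, not full GROMACS
topology syntax; bead metadata rides on structured comments so that
write → read is the identity. Pore areas on real (disordered) bilayers
depend on the occupancy radius at the ±1 lipid-footprint level; diameters
are the robust quantity. The 50 %-charged preset follows the literal
"every second unit protonated" reading, giving 12 charged units of 23.
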