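---
title: "Interface stability from simulated trajectories: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interface stability from simulated trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ifacedyn)
```

## The scientific setting

`ifacedyn` analyses the stability of the interface between the two
subunits of a protein heterodimer — the motivating system is human
microsomal triglyceride transfer protein (hMTP), whose α subunit docks
onto protein disulfide isomerase (PDI), and the question of whether a
ligand bound at PDI's b′ domain (such as 17β-estradiol) loosens that
interface. The package takes simulation *output* (structures,
trajectories, pulling records) and computes interface composition,
per-contact flexibility, and nonequilibrium free-energy estimates. It
deliberately contains no molecular-dynamics engine; the only dynamics it
implements is a one-dimensional Brownian generator used to validate the
free-energy machinery.

## Distance rules and region decomposition

Two definitions drive the composition analysis, both with *inclusive*
cutoffs:

* **interface atom pair** — two atoms, one per partner, at distance
  ≤ 5 Å in a given conformation;
* **interface contact** — two residues, one per partner, whose Cα–Cα
  distance is ≤ 7 Å in *at least one* analysed conformation (a union over
  frames, so a contact formed transiently anywhere along a trajectory
  counts).

Counts and areas are decomposed by the PDI-side domain. The canonical
domain map (author residue numbering, never renumbered) is: PDI
N-terminal 18–25, a 26–133, b 137–232, b′ 235–349, x 350–368, a′ 369–479,
C-terminal 480–508; α subunit β-barrel 19–297, α-helical 298–603,
lipid-binding 604–894. Residues in the inter-domain gaps (134–136,
233–234) report as `"unassigned"` and are tallied separately rather than
silently inflating a named region. Interface contacts are grouped into
region 1 (PDI a), region 2 (b′), region 3 (a′) and region 3′ (C-terminal);
anything else is `"other"`.

Hydrogen atoms, when present, participate in atom-pair counts by default
(`heavy_only = FALSE`), since the 5 Å rule is stated for atoms without
restriction and simulated systems carry hydrogens; crystal structures
usually lack them, so counts from the two sources are not directly
comparable either way.

## Interface area

The reference analysis used an external Voronoi-polyhedra tool for
interface areas. This package instead makes buried solvent-accessible
surface area the default (`method = "buried-sasa"`): per atom of the PDI
partner, SASA in the isolated partner minus SASA in the complex, summed
and region-decomposed. What downstream logic needs from an area metric —
non-negativity, region decomposability, exact zero for separated partners
— is preserved; absolute values are not comparable to a Voronoi method's.

SASA is computed by an own Shrake–Rupley implementation (no installed R
package provides one): each atom's accessible sphere (van der Waals radius
from a Bondi-type table, unknown elements falling back to 1.7 Å with a
warning, plus a 1.4 Å probe) is sampled with 960 deterministic
golden-spiral points. One numerical subtlety matters: a fixed point
orientation makes the estimate drift by ~1 % under rigid rotation of the
input. The point set is therefore oriented per atom in a local frame built
from its nearest-neighbour directions, which makes the estimator exactly
equivariant under rigid motion (rotation invariance then holds to floating
point, far inside the 0.5 % documented tolerance). On the two-sphere
benchmark the 960-point estimate agrees with the analytic spherical-cap
area within 2 %.

The alternative `method = "voronoi-contact"` integrates, for each
cross-partner atom pair within `r_i + r_j + 2·probe`, the area of the
shared radical-plane (power-diagram) facet clipped to the accessible
spheres, by midpoint quadrature on an equal-area polar grid. It is offered
as a contact-area-flavoured cross-check, not as a reimplementation of any
specific external tool.

## Mean-square fluctuation of distance (MSFD)

For contact *ij* observed over *N* frames,
`MSFD = (1/N) Σ_k (R_ij,k − R̄_ij)²`. The divisor is *N* — the population
variance — following the defining formula exactly; at the hundreds of
frames typical of production analyses the difference from *N*−1 is
negligible, but the choice is fixed and tested (`msfd(c(1,2,3))` is
exactly 2/3). Frame selection is exposed as a `stride` argument
(default 1, i.e. every stored frame), since "representative conformation"
schemes vary between studies.

Three rules sit on top of the per-contact values:

* **Tail exclusion** — a contact is dropped only when *both* its α-subunit
  residue lies in the flexible modeled C-terminal tail (default 886–894,
  configurable, since the exact span such a rule should cover is a
  judgement call) *and* its MSFD exceeds 14 Å² (strictly) in at least one
  condition. A large MSFD outside the tail is kept; a tail residue with
  modest MSFD is kept.
* **Condition comparison** — contacts are counted as differing when the
  MSFD gap exceeds the 1 Å² margin *strictly*; a delta of exactly 1 Å²
  falls in the neutral band. "Exceeds by 1" reads most naturally as a
  strict inequality; the margin is an argument, so the boundary convention
  is inspectable and changeable.
* **Region averages** — arithmetic means over member contacts. The
  four-region summary `all_four` is a *pooled* mean over all contacts in
  regions 1/2/3/3′ (default), because a flat average over contacts weights
  the evidence by the number of observed contacts rather than giving a
  sparsely populated region equal voice; `pooled = FALSE` gives the
  mean-of-means alternative. Empty regions are absent from the output, not
  reported as 0 — a zero average would be indistinguishable from a rigid
  region.

## Work accumulation and the Jarzynski estimate

A constant-velocity harmonic trap at stiffness k moving at velocity v
exerts `F = k(x₀ + vt − x)` on the pulled coordinate. External work is the
integral of F over the *trap* displacement, accumulated by trapezoidal
quadrature on the stored grid (the storage grid, not the integrator step,
is the only discretisation the analysis sees; record finely if the force
is rough). The free energy at pulled distance λ = vt is estimated from
replicate work values two ways:

* **cumulant2** (headline): `⟨W⟩ − β·popvar(W)/2`, the second-order
  cumulant expansion of Jarzynski's equality, exact when the work
  distribution is Gaussian (as for harmonic systems). The population
  variance is used, consistent with the MSFD convention.
* **exponential**: `−(1/β)·ln⟨e^{−βW}⟩` via log-sum-exp, the unexpanded
  equality. It is reported alongside in every `pmf_curve()`; divergence
  between the two flags a non-Gaussian work distribution, where the
  exponential average is formally exact but high-variance.

`k_B = 0.0019872041` kcal/(mol·K); temperature defaults to 300 K.
Estimation warns (never errors) below 10 replicas, the usual minimum for
work averaging. The cumulant estimate can never exceed the mean work,
which the tests assert as an invariant. Force–distance profiles use the
midpoint of two marker Cα atoms (defaults 595/591, the helix used to
orient the pull in the motivating system); the reported distance is the
displacement *magnitude* of that midpoint from its initial position, with
`projection = TRUE` for the signed projection on the pull direction, since
either reading of "distance" is defensible. A `lambda_max` truncation
confines the analysis to the early pulling window, where the pulled
subunit is still interacting and the estimates are most meaningful.

`build_spring_network()` constructs the Cα restraint network (pairs
≤ 7 Å in the initial structure, k = 10 kcal/mol/Å², rest lengths from the
initial distances) used to keep a pulled subunit internally rigid. It is a
static construction here; wiring it into an integrator is out of scope.

## The synthetic-data generators

The generators exist so that every stage has an input with a known answer;
their defaults are the package's study conditions, chosen once:

* **Toy complexes** (`make_toy_complex()`): chain-a Cα atoms on a jittered
  ~6 Å lattice, a chosen fraction of chain-b residues placed 3.8–6.8 Å
  from an anchor (inside the 7 Å rule with margin), the rest across a
  30 Å gap; every residue carries a dummy sidechain atom so atom-pair and
  area code paths see more than Cα atoms. The exact ≤ 7 Å contact set is
  emitted alongside, computed by direct enumeration at build time.
* **Fluctuating trajectories** (`make_fluctuation_trajectory()`):
  designated chain-b residues translate rigidly along their initial
  contact axis so the contact distance is `d₀ + δ_k`, with δ i.i.d.
  Gaussian (exact target variance σ²) or sinusoidal (A²/2 over whole
  periods). A residue appearing in several designated contacts moves once,
  along its first contact's axis. All other atoms stay fixed.
* **Brownian pulling** (`simulate_brownian_pull()`): overdamped
  Euler–Maruyama dynamics,
  `x ← x + (dt/γ)(−U′(x) + F_trap) + √(2k_BT·dt/γ)·ξ`, in a flat or
  harmonic well, with work accumulated at full step resolution and stored
  on a thinned grid. Closed forms: ΔF = 0 (flat) and κkλ²/(2(κ+k))
  (harmonic well κ with trap k). A stability guard rejects
  `(k+κ)·dt/γ ≥ 0.1`. Defaults: dt = 10⁻⁵ ns, and friction
  γ = 0.1 kcal·ns/(mol·Å²), set so the relaxation time γ/(κ+k) is far
  below the pull duration and the near-quasi-static regime is reachable
  within a 2 ns pull.

Every generator is a pure function of its seed.

What the generators deliberately do **not** emulate: all-atom excluded
volume, solvent, hydrogen bonding, ligand chemistry, or correlated
multi-contact motion. Passing tests therefore demonstrate that the
*statistics and rules* are implemented correctly, not that any particular
biological system behaves a given way — the headline MSFD values and PMF
magnitudes of a real 50 ns production study depend on undeposited
trajectories and are out of reach by construction.

## Problem sizes and numerical tolerances

The test suite and the acceptance script run at desk scale, sizes chosen
to give each statistical check adequate power: variance recovery uses
10⁵ frames (SE ≈ 0.01 Å² at σ = 1.5 Å), the sinusoidal limit 10⁴ frames
over whole periods, the Jarzynski closed-form check 10⁵ Gaussian work
samples (±0.05 kcal/mol), and PMF recovery 100 replicas pulled 2 Å at
1 Å/ns with dt = 10⁻⁴ ns (guard value 0.011), where the cumulant estimator
is unbiased and its sampling error is a few percent of the 20/11 kcal/mol
target. Brute-force oracle comparisons (pair counts, contact unions,
spring networks, exclusion and comparison predicates) run over 20–50
seeded fixtures each and must agree exactly. Counts are compared as
integers; areas carry a 10⁻³ Å² summation tolerance; the MSFD rigid-motion
invariance is asserted to 10⁻⁹.

## Degenerate inputs and tie-breaks

Alternate-location atoms resolve to the highest occupancy, ties to the
first listed record. Residues lacking a Cα are skipped from contact
analysis with a warning (an error only when a whole partner has none).
A one-frame trajectory is legal for contact analysis (the union
degenerates to the single-structure rule) but not for MSFD, which needs
N ≥ 2. Zero-variance work ensembles return the common work exactly under
both estimators. `pmf_curve()` at t = 0 returns exactly 0. Frame-table
trajectories are written at full `%.17g` precision so they round-trip
bit-identically; PDB output carries the format's fixed 3-decimal
precision.

## Known limitations

* The crystal-structure contact count of the motivating system can only be
  recomputed when the deposited entry (PDB 6I7S) is available locally or
  downloadable; no coordinates are bundled.
* Buried-SASA areas are one-sided (summed over the PDI partner) and not
  numerically comparable to Voronoi contact areas of external tools.
* The hydrogen-bond observations that motivate condition labels in studies
  of this kind are not detected here; a distance-only proxy would not
  reproduce them and none is claimed.
* The Brownian generator is one-dimensional by design; it produces the
  same mathematical object a steered-MD work analysis consumes, not a
  model of protein dissociation.
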