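---
title: "Modelling enzymatic degradation and mechanics of a collagen fibril"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling enzymatic degradation and mechanics of a collagen fibril}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The model

`fibrildeg` couples two simulation layers. A **dynamic Metropolis Monte
Carlo (MC) lattice model** evolves the degradation of a single collagen
fibril under the combined action of collagenase (MMP-1-like) and
gelatinase (MMP-9-like) enzymes. The degraded lattice is then mapped onto
a **coarse-grained bead-spring structure** on which a strain-controlled
tensile test is run (internally for reduced systems, or through a LAMMPS
export for full-scale production runs), connecting the *pattern* of
enzymatic damage to the fibril's mechanical integrity.

## The fibril lattice

A tropocollagen molecule is a chain of 22 axial sites (site length
13.4 nm, so one D-period of 67 nm is exactly 5 sites and one molecule is
4.4 D). Molecules stack end-to-end in columns with a 3-site (0.6 D) gap
between consecutive molecules; laterally adjacent columns are staggered by
whole D-periods, which reproduces the canonical gap/overlap banding.

The cross-section is a triangular close packing of columns grouped into
5-column microfibrils. The microfibril tile is a centre column plus its
four neighbours along the two lattice vectors; these tiles tile the
triangular lattice perfectly (the tile centres form the index-5
sublattice), so every interior column has coordination 6 and no artificial
interior voids exist. Microfibrils are arranged centred-hexagonally:
`3*m*(m-1)+1` microfibrils for `m` per edge. With the defaults (`m = 4`,
5 molecules per column) the fibril has 37 microfibrils, 185 columns, 925
chains and 20,350 sites.

A site is **on the surface** when at least one of its six lateral faces
has no intact occupant. A face is blocked by an intact site at the same
axial position in the adjacent column, or by a gap interior whose two
flanking sites are intact — gaps are grooves in the surface, not channels
into the fibril, so enzymes start confined to the outer shell and reach
deeper material only as it becomes exposed by removal. Axial fibril ends
are surface.

## Enzyme energetics (units of kT)

* Collagenase on a native (uncleaved) molecule: a single high-affinity
  well of depth `e_well` at axial index `i = 5` (counted from the C
  terminus), zero elsewhere. On a *gelatin* molecule (one with at least
  one cleaved bond): +0.5 everywhere. Sites flanking a cleaved bond are
  strictly forbidden to collagenase — such proposals are rejected before
  any energy arithmetic (the "infinite energy" is a marker, never a
  number).
* Gelatinase: 0 on native molecules, −0.5 on gelatin, at any index.

**Calibration of the well depth.** The well depth is defined
operationally: a single adsorbed collagenase should spend ≈18% of
simulation steps paused at its characteristic cleave site, the "class II
pause" statistic from single-molecule tracking. Because the Metropolis
dynamics with symmetric proposals has the Boltzmann distribution as its
unique stationary law, the pause fraction is available in closed form
(`pause_fraction_boltzmann()`), and `calibrate_well_energy()` inverts it.
On this lattice a −2 kT well yields a 26.0% stationary pause fraction (21
competing flat sites per chain: `exp(2)/(21+exp(2))`), and the 18% target
corresponds to ≈ −1.53 kT. The package default keeps `e_well = -2`; the
acceptance workflow runs the calibration first, then *measures* the pause
fraction from long independent runs — the dynamic estimate and the closed
form agree to well under a percentage point, which is the real
correctness check. The discrepancy between the printed −2 kT and the 18%
statistic cannot be resolved by any Metropolis implementation with a
22-site landscape; we attribute it to unreported structural or counting
details of the original calibration.

## Moves, cleavage and time

Each step selects one enzyme uniformly and draws an attempt type: vertical
move (probability 0.90), horizontal move (0.09), or cleave attempt (0.01).
Vertical trials go one site up or down the column (crossing gaps onto the
next molecule); horizontal trials pick one of the six lateral faces
uniformly and land at the same axial position. The uniform-face rule
replaces a literal "left/right along the surface ring" ordering because a
static ring on a ragged, evolving surface breaks proposal symmetry and
with it detailed balance; the uniform rule keeps the left/right symmetry
and makes the Boltzmann stationary distribution exact. Proposals onto
removed, occupied, non-surface or (for collagenase) cleaved-flanked sites
are blocked; all others are accepted with the Metropolis probability
`min(1, exp(-dE))`.

Real time enters through the diffusion coefficient: a vertical trial
displaces the enzyme one site with probability `p_vertical`, so matching
`MSD = 2 D t` gives `dt_attempt = p_vertical * a^2 / (2 D)` per attempt
(`a` = site length; the MSD is measured in the site-contour metric — one
move is one site — since rare gap hops cover 4 axial positions in a
single move). The default `D = 8e5` nm²/s is the order of magnitude from
single-molecule tracking of MMPs on collagen fibrils; the cited source
value is not printed in the text this model follows, so `D` is exposed as
a plain parameter. One engine step advances the clock by
`dt_attempt / n_enzymes`.

A cleave attempt in a competent state succeeds with probability
`cleave_rate * dt_attempt / p_cleave_attempt`, which makes the competent
waiting time exponential with mean `1/0.35` s. Competence:

* **Collagenase** — only at its characteristic cleave site on a native
  molecule. Two conventions are supported for the i = 4 / i = 5 tension in
  the source description; the default (`cleave_mode = "well"`) lets the
  enzyme cleave *from* the well site i = 5, severing the bond between
  sites 4 and 5 directly below it. The same bond is severed under the
  alternative `"site_below"` convention (occupy i = 4, sever the bond
  above). We default to the well convention because the binding site and
  the cleave site are the same site in the experimental picture, and
  because 66 nm from the C terminus falls inside site 5 for 13.4-nm
  sites.
* **Gelatinase** — any site of a gelatin molecule with an intact bond
  above; severs that bond.

## Fragment removal

Removal is driven by *double cuts*: a single site whose two flanking
positions are cleaved bonds (or chain ends) is disconnected and removed
immediately. A larger bond-connected fragment is removed only when it is
vertically isolated *by occupancy* — the column positions directly above
and below it are vacant or removed — and touches fewer than two intact
beads laterally. A cleaved bond alone therefore never sheds material: the
unbonded neighbour still holds the fragment in place. This is the reading
under which collagenase alone produces cleaved bonds but no mass loss, and
removal is gelatinase-driven and spatially localised, which matches the
qualitative behaviour the model is meant to reproduce (the alternative
bond-connectivity reading lets every collagenase cut shed the short
C-terminal fragment and inverts the enzyme-ratio phenomenology). The
cascade iterates to a fixed point after every cleave; enzymes standing on
removed material are relocated to uniformly random empty surface sites
(adsorption/desorption is out of scope, so enzyme counts are conserved).

Percent degradation is removed sites over initial sites × 100; production
analyses are performed at 1.1%.

## From lattice to beads

Each intact site becomes 10 collinear beads at the equilibrium bond length
`r0 = 14.7` Å (so a 22-site molecule is 220 beads, 219 bonds); a cleaved
lattice bond removes the single bridging bead-bond; a removed site removes
its ten beads. The force field is a versioned JSON parameter set of the
established coarse-grained collagen bead-spring family: two-regime bond
potential (harmonic `k0 = 17.13` kcal/mol/Å² about `r0` up to
`r1 = 18.2` Å, stiffened `k1 = 97.66` up to rupture at 21 Å, energy- and
force-continuous at the switch), 12-6 Lennard-Jones cohesion
(`eps = 6.87` kcal/mol, `sigma = 14.72` Å, energy-shifted truncation at
18 Å), and a backbone bending term implemented in cosine form
`2k(1+cos θ)`, which matches the harmonic `k(θ−π)²` curvature at the
straight configuration while avoiding an `acos` in the inner loop. These
constants were transcribed from the published force-field family, not
from a supplement we could verify; they live in
`inst/extdata/forcefield_cg_collagen.json` and every value can be
overridden.

The tensile engine integrates velocity-Verlet with a Langevin thermostat
(damp 1 ps), a per-bead speed cap at 5× the thermal speed (which prevents
the simulation collapsing at large strain, at the price of unphysical
energy dissipation right at fracture events), periodic boundaries along
the axis only, and strain control by multiplicative axial box growth with
affine remap. Stress is the virial `σ_zz` (kinetic + configurational,
tension positive) over a *nominal* volume — lateral bounding box plus one
LJ diameter times the current box length — so absolute stresses carry an
arbitrary-area scale; comparisons across systems use the same structure
and are unaffected.

# What the reduced systems do and do not establish

The built-in engine targets reduced fibrils (≤ ~15,000 beads; the
canonical reduced system is `m = 2`, 2 molecules per column: 70 chains).
Production-scale structures (925 chains × 220 beads) are supported through
`write_lammps_data()` only. Desk-scale tensile tests additionally use an
accelerated strain rate (~2.5e9 1/s instead of the reference 1e7 1/s,
which would need ~2 × 10⁶ steps per run). Consequences:

* Orderings across enzyme conditions (toughness, sliding fractions, yield
  comparisons) are meaningful and are what the test-suite asserts.
* Absolute stresses, yield strains and toughness values are *not*
  comparable to production-scale runs: the printed ~52%/~43% yield-stress
  reductions of the full 925-chain systems are out of desk reach and are
  deliberately not asserted anywhere.
* A green ordering test establishes that the degradation-pattern
  mechanism (more collagenase → more cleaved, load-free bonds at fixed
  removal) survives the mapping to mechanics; it does not validate the
  force-field constants themselves.

# Known limitations

* **Degradation-time ordering at 1.1%.** On the reduced fibril at 1.1%
  degradation the removal process is still in its transient: gelatin
  chains are accumulating, and the removal rate scales roughly with
  `n_collagenase * n_gelatinase`, which makes the 2:6 and 4:4 systems
  statistically tied. The gelatinase-dominated regime (removal rate ∝
  gelatinase count, 2:6 fastest, 6:2 slowest) emerges at deeper
  degradation — we verified the full expected ordering at 3% and 6% on
  the same reduced lattice. The acceptance test asserts the stated 1.1%
  condition regardless, and the 2:6-faster-than-4:4 clause can fail at
  that depth.
* **Emergent collagenase drift.** A burnt-bridge ratchet is built into
  the rules (after cleaving, the enzyme sits above its own cut and cannot
  recross it), but with `D ~ 0.8 µm²/s` and a 0.35 1/s competent rate the
  mean interval between cleaves by one enzyme corresponds to a diffusive
  spread larger than the entire fibril, so the +1 D-period ratchet step is
  erased by mixing and no net C→N drift is measurable; on a bounded
  fibril the long-run displacement is slightly *negative* because enzymes
  equilibrate toward the wells at i = 5, which sit below the chain
  midpoint. Observable drift would require a cleavage-to-diffusion ratio
  orders of magnitude larger than the adopted literature values. The
  acceptance test for the drift is implemented as specified and left to
  report this honestly.
* The MC fibril is finite with free axial ends; end columns expose
  low-`i` and high-`i` segments of inner microfibrils, which slightly
  enriches the accessible surface in well sites (the closed-form pause
  fraction accounts for this exactly).
* Enzyme adsorption/desorption, GAG protection, tension-dependent
  kinetics, crimp/supertwist geometry and sequence detail are out of
  scope by design.

# Numerical and design choices worth knowing

* All randomness flows through R's RNG (`set.seed()` reproduces runs
  bit-for-bit); the MD thermostat uses an internal xoshiro256+ Gaussian
  stream seeded from the R RNG for speed.
* The yield point is the first sample where the smoothed tangent modulus
  drops below 10% of the initial modulus (both the fraction and the
  smoothing window are arguments); the sliding/stretching threshold is
  the kernel-density minimum between the two bond-length modes, with a
  midpoint fallback when no clear bimodality exists. The source material
  defines neither quantity operationally, so both are config-exposed.
* Cross-sectional localisation is quantified by the Gini coefficient over
  density-map cells (one cell per microfibril by default), since the
  reference comparison is visual.
* Toughness is a trapezoidal integral of stress over strain up to a
  stated bound, reported with the bound.
* `remove_disconnected()` on a *degenerate single-column* lattice removes
  an entirely intact molecule (it has no lateral attachments by
  construction); the MC dynamics never evaluates that case spontaneously.
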