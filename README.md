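# fibrildeg

Collagen in load-bearing tissue is degraded by two families of matrix
metalloproteinases: **collagenases** (MMP-1), which cleave the native
triple helix at a single characteristic site about a quarter of the
molecule from the C terminus, and **gelatinases** (MMP-9), which bind and
digest the partially denatured ("gelatin") molecules that collagenase
cleavage creates. `fibrildeg` is for researchers in collagen
biomechanics and enzyme biophysics who want to ask: *for a fixed amount
of mass loss, how does the ratio of collagenase to gelatinase shape the
damage pattern of a single fibril — and what does that pattern do to the
fibril's strength and toughness?*

The package implements a two-layer simulation workflow:

1. **Dynamic Metropolis Monte Carlo degradation.** The fibril is a
   hierarchical lattice (tropocollagen molecules of 22 sites, D-staggered
   columns with gap/overlap banding, 5-column microfibrils packed
   centred-hexagonally; the default `m = 4` fibril has 925 chains and
   20,350 sites). Enzymes diffuse on the evolving surface and are
   accepted/rejected by the Boltzmann factor `min(1, exp(-ΔE/kT))` of the
   interaction energies: a −2 kT collagenase well at axial index `i = 5`
   on native molecules, ±0.5 kT gelatin terms, and a hard exclusion of
   collagenase from cleaved sites. Competent enzymes cleave at an overall
   rate of 0.35 s⁻¹; double-cut and detached fragments are removed, and
   percent degradation = removed/initial sites × 100.
2. **Coarse-grained tensile mechanics.** The degraded lattice maps onto a
   bead-spring structure (1 site → 10 beads at r₀ = 14.7 Å; 220 beads per
   chain) with a two-regime bond potential, Lennard-Jones cohesion and
   backbone bending. A built-in velocity-Verlet/Langevin engine runs
   strain-controlled tensile tests on reduced fibrils and records the
   virial stress σ_zz(ε); full-scale structures are exported as LAMMPS
   data files. Post-processing gives yield point, toughness
   (∫σ dε), and bond-length distributions classified into *sliding*
   (near r₀, load-free) and *stretching* (elongated, load-bearing)
   populations.

## Worked example

Degrade a reduced fibril (7 microfibrils, 70 chains) with 6 collagenases
and 2 gelatinases to 1.1% mass loss, then pull it:

```r
library(fibrildeg)
lat <- make_fixture("m2-reduced")$lattice
st  <- place_enzymes(lat, n_collagenase = 6, n_gelatinase = 2, seed = 1)
st  <- run_until(st, target_pct = 1.1)
print(st)
#> <mc_state>
#>   6 collagenase(s), 2 gelatinase(s)
#>   steps: 1.45045e+07, time: 183.1 s, degradation: 1.1039%
#>   events logged: 152
tail(time_course(st), 3)
#>    time_s percent_degraded n_cleaved_bonds n_removed_sites
#>  182.8312         1.038961             127              16
#>  183.1243         1.038961             128              16
#>  183.1243         1.103896             128              17
density_map(st, "cleaved")
#> <density_map> cleaved events: 128 over 7 cells (Gini 0.150)

beads <- lattice_to_beads(st$lattice)
beads
#> <bead_model> 15230 beads, 15049 bonds, 70 chains
ff <- force_field()
tr <- run_tensile(beads, ff,
        tensile_protocol(strain_rate = 2.5e9, max_strain = 0.55,
                         equilibration_steps = 1200, seed = 1))
yield_point(tr$curve)[c("yield_strain", "yield_stress")]
#> yield: strain 0.446, stress 1433 MPa
toughness(tr, 0.5)
#> 339 MPa
```

Reading the numbers: the 8 enzymes took 183 s of simulated time to remove
17 of 1,540 sites (1.10%), leaving 128 cleaved bonds whose cross-sectional
spread has Gini 0.15 (small = evenly distributed over the 7 microfibrils;
gelatinase-rich systems localise damage and score higher). The mapped
structure then loses 10 bead-blocks and the bridging bonds of the cleaved
sites; under an accelerated desk-scale strain rate (2.5×10⁹ s⁻¹ — the
reference production rate is 10⁷ s⁻¹) the degraded fibril yields at 45%
box strain and absorbs 339 MPa·strain of work up to 50% strain. Absolute
values at desk scale are only comparable *across systems*: re-running
with 2 collagenases : 6 gelatinases at the same 1.1% gives fewer cleaved
bonds, fewer sliding bonds and a tougher fibril, which is the central
phenomenon the package reproduces.

The four standard enzyme conditions are available as presets
(`system_preset(1)` = 4:4, `2` = 8:8, `3` = 6:2, `4` = 2:6), and a full
degrade → map → test → analyse pipeline runs via
`run_pipeline(run_config(...))` or the CLI wrapper
(`inst/cli/fibrildeg.R`, subcommands `build`, `degrade`, `export-lammps`,
`tensile`, `run-all`, `fixtures`).

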