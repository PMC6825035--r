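{
  "name": "cg-collagen-bead-spring",
  "version": 1,
  "comment": "Coarse-grained collagen bead-spring parameter set (two-regime bonds + LJ cohesion + backbone angle). Units: kcal/mol, Angstrom, fs, g/mol, K.",
  "r0": 14.7,
  "k0": 17.13,
  "k1": 97.66,
  "r1": 18.2,
  "r_break": 21.0,
  "lj_epsilon": 6.87,
  "lj_sigma": 14.72,
  "lj_cutoff": 18.0,
  "angle_k": 14.98,
  "theta0_deg": 180.0,
  "mass": 1358.0,
  "timestep_fs": 10.0,
  "temperature_K": 300.0,
  "langevin_damp_fs": 1000.0,
  "max_velocity_factor": 5.0
}
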