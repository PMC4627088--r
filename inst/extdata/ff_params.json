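{
  "_provenance": "Default coarse-grained force-field parameter set, version 1. Energies kcal/mol, lengths Angstrom, angles degrees. Functional forms follow the three-site-per-nucleotide DNA model family (bond/bend/torsion + stacking + Watson-Crick pairing + excluded volume + solvent-induced cohesion + Debye-Huckel phosphate electrostatics) and a 12-10 native-topology protein model. Native distances/angles are taken from the calibrated fiber-model build geometry; well depths are fixed here once and never tuned against simulation output.",
  "units": {
    "energy": "kcal/mol",
    "length": "angstrom",
    "angle_k": "kcal/mol/rad^2"
  },
  "kB": 0.0019872041,
  "dna": {
    "bond_k2": 60.0,
    "bond_k4": 600.0,
    "angle_k": 20.0,
    "dihedral_k1": 10.0,
    "dihedral_k3": 2.0,
    "stack_eps": 1.0,
    "pair_eps_AT": 2.0,
    "pair_eps_GC": 3.0,
    "ev_sigma": 3.2,
    "solvent_eps": 0.2,
    "solvent_r0": 13.38,
    "solvent_alpha": 0.5,
    "solvent_cutoff": 22.0,
    "solvent_on": true,
    "cross_stack_eps": 1.0
  },
  "protein": {
    "bond_k2": 100.0,
    "bond_k4": 0.0,
    "angle_k": 20.0,
    "dihedral_k1": 1.0,
    "dihedral_k3": 0.5,
    "native_eps": 2.0,
    "native_q_tolerance": 0.2,
    "ev_sigma": 4.0
  },
  "cross": {
    "elec_scale": 2.5,
    "specific_eps": 2.0,
    "specific_cutoff_mult": 2.5,
    "nonspecific_mean": 0.6,
    "nonspecific_sd": 0.1,
    "nonspecific_r0": 5.0,
    "nonspecific_cutoff": 10.0
  },
  "ev_eps": 1.0,
  "electrostatics": {
    "dielectric": 78.0,
    "coulomb_k": 332.0637,
    "cutoff_lambda_mult": 5.0
  }
}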