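{
  "_provenance": {
    "box": "simulation box 220 x 220 x 820 A, periodic, DNA along Z (Simulation protocol)",
    "temperature": "T = 300 K (Simulation protocol)",
    "gamma": "Langevin friction 0.25 in reduced units (Simulation protocol)",
    "salt_mM": "default 20 mM; study range 20-200 mM (Simulation protocol)",
    "cage": "K_cage = 100.0, C = 4.0 A; R = 0 rigid sentinel, R = Inf unconfined (DNA model / Results)",
    "classifier": "3D > 30 A; sliding: >= 70% recognition-region major-groove contact, <= 18 A, Psi < 25 deg; hopping otherwise within 30 A (Methods)",
    "minor_width": "occupied groove counted minor below 15 A (Results)",
    "nonspecific": "Gaussian eps mean 0.6, sd 0.1 (Simulation protocol)",
    "kinetics_start": "20 bp from target, 30 A from DNA surface (Results)",
    "success": "specific complex formed at Q_sp > 0.8 (Results)"
  },
  "dna_length_bp": 200,
  "box": [220, 220, 820],
  "temperature": 300,
  "gamma": 0.25,
  "dt": 0.01,
  "salt_mM": 20,
  "cage": { "radius": "inf", "k": 100.0, "c": 4.0, "continuity_shift": false },
  "classifier": {
    "d_3d": 30, "d_slide": 18, "contact_min": 0.7, "psi_max": 25,
    "contact_dist": 10, "minor_width": 15
  },
  "kinetics": {
    "offset_bp": 20, "radial": 30,
    "success_threshold": 0.8, "sustain_frames": 10,
    "nonspecific_mean": 0.6, "nonspecific_sd": 0.1
  },
  "protein": {
    "n_residues": 48,
    "recognition_range": [17, 32]
  }
}
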