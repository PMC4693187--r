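{
  "comment": "SYNTHETIC user-supplied thermodynamic configuration for the ammonia-assimilation case study. Standard free energies (kJ/mol) and clamped cytoplasmic concentrations (mol/L) are synthetic stand-ins of literature-like magnitude, chosen so that the qualitative case-study structure exists (GDH near equilibrium / infeasible at low NH3 while GS/GOGAT remains feasible). They are NOT measured values.",
  "dg0": {
    "GDH": -30.0,
    "GS": -25.0,
    "GOGAT": -40.0
  },
  "conc": {
    "GLU": 1e-3,
    "GLN": 1e-3,
    "NH3": 1e-3,
    "AKG": 1e-2,
    "NADPH": 1e-4,
    "NADP": 1e-4,
    "ATP": 5e-3,
    "ADP": 5e-4,
    "Pi": 5e-3
  }
}
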