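{
  "version": "cgcam-ff-1",
  "comment": "Coarse-grained force-field parameter set. Backbone geometry and well placements follow standard three-bead conventions; pairwise contact strengths and burial propensities are generated from a normalized Kyte-Doolittle hydrophobicity scale (gamma_ij = g0 + g1*(h_i+h_j)/2; burial wells favor buried hydrophobics). Energies kcal/mol, lengths Angstrom.",
  "masses": { "cb": 10.0, "o": 16.0 },
  "backbone": {
    "k_con": 60.0,
    "r_ca_ca": 3.816, "r_ca_o": 2.44, "r_o_ca": 2.83, "r_ca_cb": 1.54,
    "k_chain": 8.0, "theta0_deg": 114.6,
    "k_chi": 0.2, "chi0": 16.0,
    "rama": {
      "A": [1.6, 1.2],
      "phi0_deg": [50.0, -170.0],
      "kappa": [4.0, 2.0]
    },
    "k_excl": 20.0, "sig_ca": 4.0, "sig_cb": 4.0, "excl_min_sep": 2
  },
  "contact": {
    "eta": 5.0, "r_direct": [4.5, 6.5], "r_water": [6.5, 9.5],
    "water_fraction": 0.4, "min_sep": 5,
    "gamma_g0": 0.1, "gamma_g1": 0.5
  },
  "burial": {
    "eta_density": 1.5, "r_density": 9.0, "eta_burial": 2.0,
    "wells_lo": [0.0, 3.0, 6.0], "wells_hi": [3.0, 6.0, 9.0],
    "beta_scale": 0.3, "beta_middle": 0.15, "min_sep": 2
  },
  "hbond": {
    "helical": { "gamma": 1.5, "r0": 6.2, "sigma": 0.6 },
    "beta": { "gamma": 0.5, "r0": 5.2, "sigma": 0.6, "min_sep": 6 },
    "pap": { "gamma": 0.2, "r1": 4.5, "r2": 6.5, "eta": 5.0, "min_sep": 6 }
  },
  "hydrophobicity_kd": {
    "A": 1.8, "R": -4.5, "N": -3.5, "D": -3.5, "C": 2.5, "E": -3.5,
    "Q": -3.5, "G": -0.4, "H": -3.2, "I": 4.5, "L": 3.8, "K": -3.9,
    "M": 1.9, "F": 2.8, "P": -1.6, "S": -0.8, "T": -0.7, "W": -0.9,
    "Y": -1.3, "V": 4.2
  }
}
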