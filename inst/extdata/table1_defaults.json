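{
  "parameters": {
    "D_n": 1e-07,
    "chi": 2e-03,
    "D_c": 2.88e-03,
    "r_n": 0.924,
    "r_m": 0.924,
    "r_max": 2,
    "a_c_I": 1e-08,
    "kappa": 1e-06,
    "k_1": 1.81e+07,
    "delta_n": 0.02,
    "delta_m": 0.06,
    "k_c": 4e-13,
    "a_c_II": 1e-08,
    "delta_c": 5e-04,
    "eta_I": 0.5,
    "eta_II": 2,
    "a_c_III": 2e+08,
    "k_rho_max": 10,
    "a_c_IV": 1e-09,
    "delta_rho": 6e-06,
    "rho_t": 1.02,
    "mu_1": 100,
    "mu_2": 100,
    "xi": 0.0044,
    "R_force": 0.3,
    "E_mod": 32,
    "nu": 0.49,
    "zeta": 900,
    "N_bar": 1e+04,
    "M_bar": 0,
    "c_bar": 0,
    "rho_bar": 0.1125,
    "c_tilde": 1e-08
  },
  "units": {
    "D_n": "cm^5/(cells day)  cell-density-dependent (myo)fibroblast diffusion",
    "chi": "cm^5/(g day)  chemotactic coefficient",
    "D_c": "cm^2/day  signaling-molecule diffusion",
    "r_n": "cm^(3q)/day  fibroblast proliferation rate",
    "r_m": "cm^(3q)/day  myofibroblast proliferation rate",
    "r_max": "-  proliferation enhancement factor",
    "a_c_I": "g/cm^3  half-maximal enhancement concentration",
    "kappa": "cm^3/cells  crowding factor",
    "k_1": "cm^3/(g day)  differentiation rate",
    "delta_n": "1/day  fibroblast apoptosis rate",
    "delta_m": "1/day  myofibroblast apoptosis rate",
    "k_c": "g/(cells day)  signaling-molecule secretion rate",
    "a_c_II": "g/cm^3  secretion-inhibition concentration",
    "delta_c": "cm^6/(cells g day)  signaling MMP-cleavage coefficient",
    "eta_I": "-  myofibroblast fraction in secretion rates",
    "eta_II": "-  myofibroblast fraction in MMP rates",
    "a_c_III": "cm^3/g  MMP-inhibition concentration",
    "k_rho_max": "-  collagen secretion enhancement",
    "a_c_IV": "g/cm^3  half-inhibition concentration of the enhancement",
    "delta_rho": "cm^6/(cells g day)  collagen MMP-cleavage coefficient",
    "rho_t": "g/cm^3  total tissue mass density",
    "mu_1": "N day/cm^2  shear viscosity",
    "mu_2": "N day/cm^2  bulk viscosity",
    "xi": "N g/(cells cm^2)  cell force constant",
    "R_force": "g/cm^3  body-force-inhibiting constant",
    "E_mod": "N/(cm^2 (g/cm^3)^0.5)  Young's-modulus prefactor (stiffness E sqrt(rho))",
    "nu": "-  Poisson's ratio",
    "zeta": "cm^6/(cells g day)  rate of morphoelastic change",
    "N_bar": "cells/cm^3  equilibrium fibroblast density",
    "M_bar": "cells/cm^3  equilibrium myofibroblast density (0)",
    "c_bar": "g/cm^3  equilibrium signaling concentration (0)",
    "rho_bar": "g/cm^3  equilibrium collagen density",
    "c_tilde": "g/cm^3  initial wound signaling concentration"
  }
}
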