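# Default channel parameter set for the SNc dopaminergic neuron model.
# Units: voltages mV, slopes mV, time constants ms, conductance densities
# pS/um^2, calcium mM. Sign convention: membrane currents outward-positive,
# I = gmax * m^a * h^b * (V - erev).
# Every constant the model uses lives here so a single edit corrects it.
channels:
  Na:
    erev: 60.0
    m: {v50: -28.0, k: 8.0, exponent: 3, tau: na_m}
    h: {v50: -50.0, k: -10.0, exponent: 1, tau: na_h}
    gmax: {somadendritic: 75.0, ais: 4000.0, axon: 400.0}
  KDR:
    erev: -90.0
    m: {v50: -30.0, k: 9.0, exponent: 4, tau: kdr_m}
    gmax: {somadendritic: 150.0, ais: 4000.0, axon: 400.0}
  A:
    erev: -90.0
    # activation v50 is derived: v50_m = v50_h + 50 (coupled gates); both
    # kinetics voltage-independent with tau_m = tau_h / 50
    m: {k: 7.0, exponent: 1, tau: ia_linked}
    h: {k: -7.0, exponent: 1, tau: ia_linked}
    v50_h_range: [-78.0, -62.0]
    tau_h_range: [15.0, 150.0]
    gmax_range: [15.0, 150.0]
    gmax: {somadendritic: 82.5, ais: 0.0, axon: 0.0}
  H:
    erev: -40.0
    m: {k: -7.25, exponent: 1, tau: h_m}
    v50_range: [-100.0, -80.0]
    gmax_range: [0.25, 2.5]
    gmax: {somadendritic: 1.375, ais: 0.0, axon: 0.0}
  CaL:
    erev: 120.0
    m: {v50: -31.0, k: 7.0, exponent: 1, tau: cal_m}
    gmax: {somadendritic: 1.0, ais: 0.0, axon: 0.0}
  SK:
    erev: -90.0
    hill: {kd: 0.00019, n: 4}
    gmax: {somadendritic: 0.125, ais: 0.0, axon: 0.0}
  leak:
    erev: -50.0
coupling:
  # half-inactivation of I_A forced to co-vary with I_H activation v50
  v50_slope: 0.814
  v50_intercept: 3.36
  # I_A activation 50 times faster than inactivation, v50 shifted +50 mV
  ia_tau_ratio: 50.0
  ia_v50_shift: 50.0
passive:
  axial_resistivity: 150.0      # ohm cm
  specific_capacitance: 0.75    # uF/cm^2
  specific_membrane_resistance: 100000.0  # ohm cm^2
  e_leak: -50.0                 # mV
calcium:
  shell_depth: 0.1    # um
  decay_tau: 5.0      # ms
  baseline: 0.0001    # mM
  buffering: 0.025    # free fraction of influx (rapid-buffer approximation)
defaults:
  # central grid values used when a biophysical parameter set is not supplied
  g_A: 82.5
  g_H: 1.375
  v50_h_act: -90.0
  tau_h_A: 82.5
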