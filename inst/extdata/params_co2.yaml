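# Default parameter set of the carbon-dioxide-based batch fermentation model.
# Units: kS gS/L CO2, kE gE/L CO2, KS g/L, Cpmax L CO2/gS, kV ppm VDK/L CO2;
# a, b are the coefficients of mu_max = a*ln(T) + b and c, d, e those of
# r_VDK = c*T^2 + d*T + e (rates in 1/h, T in degrees Celsius, calibrated
# over 17-28 C).
model: co2
parameters:
  kS: 3.72e-1
  kE: 1.62e-1
  KS: 12.0
  Cpmax: 2.18
  kV: 1.74e-2
  a: 1.41
  b: -3.89
  c: -3.0e-4
  d: 1.6e-2
  e: -1.75e-1
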