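# Default parameter set of the biomass-based batch fermentation model.
# Units: kS gS/gX, kE gE/gX, Smin g/L, deltaX 1/h, kV ppm VDK/gX,
# kCO2 L CO2/gX; a, b are the coefficients of mu_max = a*ln(T) + b and
# c, d those of r_VDK = c*ln(T) + d (rates in 1/h, T in degrees Celsius,
# calibrated over 17-28 C).
model: biomass
parameters:
  kS: 15.3
  kE: 6.31
  Smin: 13.1
  deltaX: 1.67e-2
  kV: 6.51e-1
  kCO2: 37.1
  a: 4.00e-1
  b: -1.1
  c: 2.50e-2
  d: -5.60e-2
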