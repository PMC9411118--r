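# Published coefficient sets predicting photosynthetic biochemistry from
# leaf nutrient concentrations. All models are on the natural-log scale:
#   trait = exp(intercept + lnP*ln(P) + lnN*ln(N) [+ lnN_lnP*ln(N)*ln(P)])
# Units: mass basis nmol g-1 s-1 with N,P in mg g-1; area basis
# umol m-2 s-1 with N,P in g m-2; Ma in g m-2.

# Set used inside the land-surface model experiment (no N x P interaction);
# the area-based equations are independent fits to the raw area-based data,
# not conversions of the mass-based ones.
methods:
  Vcmax_mass: {intercept: 4.4490, lnP: 0.3472, lnN: 0.49078}
  Jmax_mass:  {intercept: 5.4944, lnP: 0.3735, lnN: 0.4144}
  Vcmax_area: {intercept: 4.308, lnP: 0.298, lnN: 0.197}
  Jmax_area:  {intercept: 5.139, lnP: 0.325, lnN: 0.112}

# Full-dataset multiple-regression set including the N x P interaction
# (recommended for biosphere models; gives a leaf-P effect on GPP about
# 15% stronger than the set above).
table2:
  Vcmax_mass: {intercept: 4.636, lnN: 0.453, lnP: -0.546, lnN_lnP: 0.321, r2: 0.42}
  Jmax_mass:  {intercept: 5.535, lnN: 0.388, lnP: -0.436, lnN_lnP: 0.295, r2: 0.47}
  Amass:      {intercept: 2.998, lnN: 0.513, lnP: -0.547, lnN_lnP: 0.294, r2: 0.35}
  Ma:         {intercept: 6.484, lnN: -0.598, lnP: 0.461, lnN_lnP: -0.214, r2: 0.51}
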