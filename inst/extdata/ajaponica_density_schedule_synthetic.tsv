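# Synthetic ontogenetic relative-density schedule (SYNTHETIC STAND-IN).
# Maps developmental progress (age_fraction = age / pelagic larval duration)
# to the ratio of larval density to seawater density at the upper
# thermocline, emulating the published Anguilla japonica specific-gravity
# ontogeny transferred onto the bonefish larval duration. The numeric nodes
# here are reconstructed, not measured: the age-0 ratio is chosen so that
# standard Stokes' law (radius 1e-4 m, seawater density 1024.4 kg/m3,
# viscosity 0.959e-3 Pa s) gives the reported ~8.5 m/day hatchling buoyancy
# rate, and buoyancy decays monotonically to neutral by ~80% of the larval
# duration ("nearly neutral specific gravity on reaching the thermocline").
# Replace with a measured table (same two columns) when available.
age_fraction	density_ratio
0.00	0.99578
0.05	0.99622
0.10	0.99668
0.20	0.99750
0.30	0.99830
0.40	0.99900
0.50	0.99950
0.60	0.99980
0.70	0.99995
0.80	1.00000
1.00	1.00000
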