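# ELBA coarse-grain force-field parameter set
#
# Units are fixed package-wide: nm, kJ/mol, amu, amu nm^2, Debye,
# elementary charge, degrees.
#
# Functional-form conventions (flip here, not in code):
#   bond       U = (kb/2) (r - r0)^2            [prefactor: half]
#   angle      selected by angle_style below:
#                theta:  U = (ka/2) (th - th0)^2        [harmonic]
#                cosine: U = (ka/2) (cos th - cos th0)^2
#   restraint  U = kd (1 - cos delta)
#   r0 rule    r0 = (sigma_i + sigma_j) / 2
#
# Shifted-force truncation is applied to the Lennard-Jones and all
# electrostatic terms; dipole-dipole interactions use a C1 cubic switch
# between switch_fraction*cutoff and cutoff.

# `mass` is the inertial site mass entering the equations of motion
# (the water value is tuned to reproduce the experimental diffusion
# coefficient); `mass_phys` is the mass of the represented atom group,
# used for density/volume bookkeeping.  The two coincide for lipid
# sites, whose masses sum to the physical molecular weights.

[sites]
# name       sigma  epsilon  mass  charge  dipole  inertia  mass_phys
choline      0.52   6.0      90    0.7     0.0     0        90
amine        0.47   3.5      42    0.7     0.0     0        42
phosphate    0.46   6.0      90    -0.7    0.0     0        90
glycerol     0.45   4.0      62    0.0     2.0     10       62
ester        0.45   4.0      62    0.0     3.0     10       62
tail         0.47   1.0      42    0.0     0.0     0        42
water        0.30   1.95     40    0.0     2.3     1        18.015

[hbond]
# hydrogen-bonding pair scalings s_ij (>= 1); pairs not listed use 1
water   phosphate  1.4
water   ester      1.3
water   glycerol   1.2
amine   phosphate  1.5
amine   ester      1.5
amine   water      1.3
amine   glycerol   1.2

[bonded]
angle_style        cosine
kb                 1260
ka                 30
kd                 10
theta_saturated    180
theta_unsaturated  120
theta_head         90
theta_branch       120

[cutoffs]
cutoff_ww        0.9
cutoff_other     1.2
switch_fraction  0.9
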