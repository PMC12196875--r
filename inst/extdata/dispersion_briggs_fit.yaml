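# Default Gaussian-plume dispersion coefficient table (SYNTHETIC stand-in).
#
# Pure power laws  sigma_y = gamma1 * x^alpha1,  sigma_z = gamma2 * x^alpha2
# (x and sigma in metres), by Pasquill stability class A-F and downwind
# distance regime. These are log-log least-squares fits to the Briggs
# open-country interpolation formulas (Briggs 1973, as tabulated in
# Hanna, Briggs & Hosker 1982), NOT the GB/T 3840-1991 regression table,
# which is an external national standard not redistributed here. Users
# holding the standard should override this file via the `table` argument
# of stability_param_table()/load_dispersion_table().
#
# Fit ranges: "near" regime fitted over 10-1000 m; "far" regime exponent
# fitted over 1000-10000 m with the coefficient chosen so the two curves
# meet exactly at 1000 m. Worst-case deviation from the Briggs curves in
# the 20-250 m screening band is ~5% (class D sigma_z), <1.1% elsewhere.
A:
  - {x_min: 10, x_max: 1000, gamma1: 0.225834, alpha1: 0.992024, gamma2: 0.200000, alpha2: 1.000000}
  - {x_min: 1000, x_max: 10000, gamma1: 0.510794, alpha1: 0.873872, gamma2: 0.200000, alpha2: 1.000000}
B:
  - {x_min: 10, x_max: 1000, gamma1: 0.164243, alpha1: 0.992024, gamma2: 0.120000, alpha2: 1.000000}
  - {x_min: 1000, x_max: 10000, gamma1: 0.371487, alpha1: 0.873872, gamma2: 0.120000, alpha2: 1.000000}
C:
  - {x_min: 10, x_max: 1000, gamma1: 0.112917, alpha1: 0.992024, gamma2: 0.084150, alpha2: 0.984538}
  - {x_min: 1000, x_max: 10000, gamma1: 0.255397, alpha1: 0.873872, gamma2: 0.294898, alpha2: 0.802999}
D:
  - {x_min: 10, x_max: 1000, gamma1: 0.082121, alpha1: 0.992024, gamma2: 0.078722, alpha2: 0.914207}
  - {x_min: 1000, x_max: 10000, gamma1: 0.185743, alpha1: 0.873872, gamma2: 0.723412, alpha2: 0.593112}
E:
  - {x_min: 10, x_max: 1000, gamma1: 0.061591, alpha1: 0.992024, gamma2: 0.034746, alpha2: 0.954961}
  - {x_min: 1000, x_max: 10000, gamma1: 0.139307, alpha1: 0.873872, gamma2: 0.739106, alpha2: 0.512362}
F:
  - {x_min: 10, x_max: 1000, gamma1: 0.041061, alpha1: 0.992024, gamma2: 0.018531, alpha2: 0.954961}
  - {x_min: 1000, x_max: 10000, gamma1: 0.092872, alpha1: 0.873872, gamma2: 0.394190, alpha2: 0.512362}
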