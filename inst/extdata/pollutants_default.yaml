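# Default pollutant property registry: the four priority aromatic VOCs
# assessed for odor risk during waste excavation. Every constant here is a
# default, overridable by supplying your own registry file to load_registry().
#
# Units as loaded (converted to SI internally by load_registry):
#   henry           - dimensionless air/water Henry's Law constant at 25 C
#   koc             - organic-carbon partition coefficient, cm3/g
#   odor_threshold  - olfactory threshold, mg/m3 (Chinese triangle odor bag
#                     method compilations; same values as GB 14554-1993
#                     supporting literature)
#   wf_slope        - Weber-Fechner slope k in OI = k*log10(OAV) + B
#   wf_intercept    - Weber-Fechner intercept B
#   screening_value - GB 36600-2018 first-category soil risk screening value,
#                     mg/kg
#
# Sources per constant:
#   henry/koc: HJ 25.3-2019 appendix-style physicochemical tables
#     (dimensionless H at 25 C; Koc in cm3/g). Literature-standard values.
#   wf_slope/wf_intercept: literature-informed defaults, user-overridable.
#     B = 1.0 places odor intensity at Level 1 ("slight perception") exactly
#     at the olfactory threshold (OAV = 1); slopes are in the 1.2-1.5 per
#     decade range reported for single aromatic odorants.
#   screening_value: GB 36600-2018 first-category values; the ethylbenzene
#     value (28 mg/kg) is the binding one for this assessment.
ethylbenzene:
  henry: 0.323
  koc: 446.0
  odor_threshold: 0.085
  wf_slope: 1.35
  wf_intercept: 1.0
  screening_value: 28.0
toluene:
  henry: 0.272
  koc: 234.0
  odor_threshold: 0.403
  wf_slope: 1.38
  wf_intercept: 1.0
  screening_value: 1200.0
styrene:
  henry: 0.112
  koc: 446.0
  odor_threshold: 0.158
  wf_slope: 1.25
  wf_intercept: 1.0
  screening_value: 1290.0
m/p-xylene:
  henry: 0.290
  koc: 407.0
  odor_threshold: 0.431
  wf_slope: 1.40
  wf_intercept: 1.0
  screening_value: 570.0
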