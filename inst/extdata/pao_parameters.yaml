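# Uncertain-input database for the PAO anaerobic-aerobic metabolic model.
#
# 39 records across five groups: 12 metabolic parameters, 9 kinetic
# parameters, 6 Arrhenius temperature coefficients, 10 initial / influent
# conditions and 2 environmental design variables (T, pH).
#
# Measurement collections are SYNTHETIC literature-emulation data: counts and
# dispersion are patterned on the published EBPR metabolic-model corpus
# (Smolders / Oehmen / Zeng / Filipe / Brdjanovic / Lanham model families and
# the reviews citing them), but the individual values were curated for this
# package and are not transcriptions of any single source.  Edit freely; the
# range rules (50/25/5 % variability by measurement count, range extension to
# the observed min/max, Erlang fitting beyond 50 points) are applied by the
# package at load time, never stored here.
#
# Fields per record:
#   name, group, units, measurements (possibly empty),
#   fixed_bounds: [lower, upper]        -> sampled uniformly, overrides rules
#   dirichlet: {alpha, coupled_group}   -> simplex weight within a group
parameters:
  - name: K_1
    group: metabolic
    units: mol ATP / C-mol biomass (acetyl-CoA route)
    measurements: [1.64, 1.85]
  - name: K_2
    group: metabolic
    units: mol ATP / C-mol biomass (propionyl-CoA route)
    measurements: [1.96]
  - name: delta
    group: metabolic
    units: mol ATP / mol NADH2
    measurements: [1.70, 1.85, 2.00]
  - name: epsilon
    group: metabolic
    units: mol ATP / P-mol PO4 transported
    measurements: [0.25, 0.31]
  - name: K_HAc
    group: metabolic
    units: C-mmol/l
    measurements: [0.16]
  - name: K_HPr
    group: metabolic
    units: C-mmol/l
    measurements: [0.25]
  - name: K_PO4
    group: metabolic
    units: P-mmol/l
    measurements: [0.020, 0.031]
  - name: K_PHA
    group: metabolic
    units: C-mol / C-mol (PHA fraction, anabolic use)
    measurements: [0.010]
  - name: K_Gly
    group: metabolic
    units: C-mol / C-mol (glycogen fraction)
    measurements: [0.010]
  - name: K_fPHA
    group: metabolic
    units: C-mol / C-mol (PHA fraction, degradation)
    measurements: [0.010, 0.015]
  - name: K_PP
    group: metabolic
    units: P-mol / C-mol (poly-P fraction)
    measurements: [0.010]
  - name: K_O2
    group: metabolic
    units: mmol O2 / l
    measurements: [0.0031, 0.0063]
  - name: q_HAc
    group: kinetic
    units: C-mol / C-mol / h at 20 C
    measurements: [0.1912, 0.1977, 0.2295, 0.209, 0.2418, 0.1985, 0.1671,
                   0.1726, 0.2135, 0.1887, 0.1877, 0.206, 0.233, 0.167,
                   0.1674, 0.2001, 0.1966, 0.2289, 0.1952, 0.147, 0.1636,
                   0.196, 0.1449, 0.1478, 0.1656, 0.2172, 0.234, 0.1744,
                   0.2331, 0.2121, 0.1682, 0.2121, 0.2275]
  - name: q_HPr
    group: kinetic
    units: C-mol / C-mol / h at 20 C
    measurements: [0.142, 0.178, 0.185, 0.196, 0.158, 0.221]
  - name: m_ATP_an
    group: kinetic
    units: mol ATP / C-mol / h at 20 C
    measurements: [0.0022, 0.0028, 0.0031, 0.0039]
  - name: q_PHA
    group: kinetic
    units: C-mol / C-mol / h at 20 C
    measurements: [0.118, 0.135, 0.152, 0.166, 0.141, 0.172, 0.129, 0.158]
  - name: q_Gly
    group: kinetic
    units: C-mol / C-mol / h at 20 C
    measurements: [0.052, 0.061, 0.068, 0.075, 0.081, 0.066, 0.088]
  - name: q_PP
    group: kinetic
    units: P-mol / C-mol / h at 20 C
    measurements: [0.0426, 0.0269, 0.0412, 0.0649, 0.0695, 0.0411, 0.0249,
                   0.056, 0.0382, 0.0492, 0.0258, 0.0608, 0.022, 0.0624,
                   0.061, 0.1112, 0.0394, 0.0594, 0.0517, 0.0926, 0.0372,
                   0.038, 0.0344, 0.0277, 0.0483, 0.0413, 0.0686, 0.0289,
                   0.0718, 0.0855, 0.0149, 0.0635, 0.0374, 0.0785, 0.0667,
                   0.0538, 0.0327, 0.0319, 0.0487, 0.0339, 0.0815, 0.0453,
                   0.0676, 0.0554, 0.0808, 0.104, 0.0637, 0.0379, 0.0378,
                   0.0431, 0.0661, 0.0576, 0.0623, 0.0609, 0.028, 0.0299,
                   0.049, 0.0395, 0.0864, 0.0535, 0.0909, 0.0593, 0.0405,
                   0.0577, 0.0716, 0.0369, 0.0484, 0.0594, 0.0747, 0.0414,
                   0.0305, 0.042, 0.0585, 0.0584, 0.0582, 0.0406, 0.0485,
                   0.0737, 0.058, 0.0429, 0.0489, 0.0679, 0.0676, 0.0109,
                   0.0372, 0.0399, 0.044, 0.054, 0.0333, 0.0486]
  - name: m_ATP_ox
    group: kinetic
    units: mol ATP / C-mol / h at 20 C
    measurements: [0.0046, 0.0052, 0.0060, 0.0066, 0.0074]
  - name: f_Gly_max
    group: kinetic
    units: C-mol / C-mol biomass
    measurements: [0.30, 0.36, 0.42, 0.47, 0.51, 0.55]
  - name: f_PP_max
    group: kinetic
    units: P-mol / C-mol biomass
    measurements: [0.42, 0.47, 0.50, 0.54, 0.58]
  - name: theta_qVFA
    group: arrhenius
    units: per C (anaerobic VFA uptake)
    measurements: [1.101]
  - name: theta_mATP_an
    group: arrhenius
    units: per C (anaerobic maintenance)
    measurements: [1.057]
  - name: theta_qPHA
    group: arrhenius
    units: per C (aerobic PHA degradation)
    measurements: [1.087]
  - name: theta_qGly
    group: arrhenius
    units: per C (aerobic glycogen formation)
    measurements: [1.071]
  - name: theta_qPP
    group: arrhenius
    units: per C (aerobic poly-P formation)
    measurements: [1.046]
  - name: theta_mATP_ox
    group: arrhenius
    units: per C (aerobic maintenance)
    measurements: [1.071]
  - name: S_VFA_i
    group: initial_condition
    units: C-mmol/l total influent VFA
    measurements: [1.02, 1.18, 1.29, 1.37, 1.46, 1.50, 1.55, 1.63, 1.71,
                   1.82, 1.94, 2.05]
  - name: r_HAc_HPr_i
    group: initial_condition
    units: C-mol HAc / C-mol VFA
    measurements: [0.51, 0.58, 0.63, 0.67, 0.70, 0.74, 0.78, 0.81]
  - name: r_P_C_i
    group: initial_condition
    units: P-mol PO4 / C-mol VFA
    measurements: [1.05, 1.22, 1.38, 1.50, 1.58, 1.71, 1.86, 1.98]
  - name: X_PAO_i
    group: initial_condition
    units: C-mmol/l
    measurements: [4.02, 4.11, 4.19, 4.26, 4.31, 4.38, 4.43, 4.47, 4.55,
                   4.61, 4.68, 4.74, 4.80, 4.86, 4.92]
  - name: f_PHA_i
    group: initial_condition
    units: C-mol / C-mol biomass (total PHA)
    measurements: [0.08, 0.11, 0.14, 0.16, 0.19, 0.22]
  - name: w_PHB_i
    group: initial_condition
    units: fraction of total PHA
    measurements: []
    dirichlet:
      alpha: 1.0
      coupled_group: pha_fractions
  - name: w_PHV_i
    group: initial_condition
    units: fraction of total PHA
    measurements: []
    dirichlet:
      alpha: 1.0
      coupled_group: pha_fractions
  - name: w_PH2MV_i
    group: initial_condition
    units: fraction of total PHA
    measurements: []
    dirichlet:
      alpha: 1.0
      coupled_group: pha_fractions
  - name: f_Gly_i
    group: initial_condition
    units: C-mol / C-mol biomass
    measurements: [0.25, 0.31, 0.36, 0.42, 0.48]
  - name: f_PP_i
    group: initial_condition
    units: P-mol / C-mol biomass
    measurements: [0.18, 0.24, 0.30, 0.35, 0.40]
  - name: T
    group: environmental
    units: C
    measurements: []
    fixed_bounds: [10.0, 30.0]
  - name: pH
    group: environmental
    units: pH units
    measurements: []
    fixed_bounds: [6.0, 7.5]
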