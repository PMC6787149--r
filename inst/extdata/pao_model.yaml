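# Model definition: stoichiometric constants and numerical settings for the
# anaerobic-aerobic PAO metabolic model (10 components, 10 kinetic
# processes).  Values are curated in the style of the classical
# acetate/propionate PAO model family (Smolders-type anaerobic acetate
# stoichiometry, Oehmen-type propionate extension, Zeng-type carbon-source
# dependence of the PHA split, Filipe-type pH dependence of the VFA
# transport energy, Lanham-type sequential maintenance, Murnleitner-type
# growth on the PHA-degradation surplus).  They are package-curated
# (synthetic) numbers, not transcriptions of any single publication; carbon
# and phosphorus closure of every process column is enforced at load time.
stoichiometry:
  hac_uptake:
    y_gly: 0.50          # C-mol glycogen consumed / C-mol HAc (pH-independent)
    y_pha_total: 1.33    # C-mol PHA formed / C-mol HAc
    co2: 0.17            # balance: 1 + y_gly - y_pha_total
    pha_split: [0.90, 0.10, 0.00]   # PHB, PHV, PH2MV from acetate
  hpr_uptake:
    y_gly_ref: 0.33      # C-mol glycogen / C-mol HPr at pH 7
    y_gly_ph_slope: 0.05 # per pH unit; glycolytic demand rises with pH
    co2: 0.11            # fixed; y_pha_total = 1 + y_gly(pH) - co2
    pha_split: [0.10, 0.60, 0.30]   # PHB, PHV, PH2MV from propionate
  transport_atp:         # ATP / C-mol VFA across the membrane, linear in pH
    slope: 0.16
    intercept: -0.7945
  p_release_extra: 0.25  # ATP / C-mol VFA beyond transport (activation net)
  atp_stoich:
    nadh_per_pha: 1.125  # mol NADH2 / C-mol PHA fully oxidized
    nadh_per_gly: 1.0    # mol NADH2 / C-mol glycogen fully oxidized
    gly_atp_an: 0.50     # mol ATP / C-mol glycogen glycolysed anaerobically
    an_maint_gly_pha: 0.67  # C-mol PHB formed / C-mol glycogen, anaerobic maintenance
  aerobic:
    y_pha_gly: 1.12      # C-mol PHA consumed / C-mol glycogen formed
  aeration:
    kla: 10.0            # 1/h, aerobic-phase oxygen transfer coefficient
    o2_sat: 0.25         # mmol O2/l saturation under controlled aeration
  o2_per_co2: 1.0        # mol O2 consumed / C-mol CO2 respired
numerics:
  k_switch: 1.0e-4       # C-mmol/l, smooth sequential-maintenance switch
  rtol: 1.0e-6
  atol: 1.0e-9
  t_ref: 20.0            # C, Arrhenius reference temperature
  grid_points: 301       # 1-minute output resolution over the 5 h cycle
  cycle_hours: 5.0
  anaerobic_hours: 2.5
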