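# Default model configuration: H-CHOP vs R-CHOP partitioned survival
# cost-effectiveness model for treatment-naive DLBCL (all monetary values
# USD; survival-model time in years).
settings:
  cycle_length_days: 21
  horizon_years: 10
  discount_rate: 0.05
  days_per_year: 365.25

survival:
  time_unit: years
  hchop:
    os:  {family: lognormal, meanlog: 3.284, sdlog: 1.938}
    pfs: {family: lognormal, meanlog: 2.998, sdlog: 1.884}
  rchop:
    os:  {family: lognormal, meanlog: 2.925, sdlog: 1.843}
    pfs: {family: lognormal, meanlog: 3.007, sdlog: 2.195}

costbook:
  bsa_m2: 1.73
  exchange_rate_cny_per_usd: 7.2338
  drugs:
    hanlikang:        {price: 193.09, unit_mg: 100}
    mabthera:         {price: 253.57, unit_mg: 100}
    cyclophosphamide: {price: 26.61,  unit_mg: 1000}
    # doxorubicin priced with the anthracycline per-10-mg list entry
    doxorubicin:      {price: 10.88,  unit_mg: 10}
    vincristine:      {price: 38.29,  unit_mg: 1}
    prednisone:       {price: 1.61,   unit_mg: 5}
    # premedication drugs: itemised prices; covered by the per-cycle
    # preventive-medication administration line, not costed separately
    acetaminophen:    {price: 5.52,   unit_mg: 100}
    diphenhydramine:  {price: 4.70,   unit_mg: 20}
    dexamethasone:    {price: 0.99,   unit_mg: 5}
  administration:
    hospitalization: 19.35
    preventive_medication: 67.58
    infusion: 5.26
  labs:
    ecg: 3.73
    hematology: 3.46
    serum_chemistry: 23.50
    hepatic_renal: 18.07
    immunoglobulin: 8.72
    coagulation: 9.20
    urinalysis: 4.15
    echocardiography: 39.12
    ct: 308.81
  ae_costs:
    leukopenia: 118.70
    neutropenia: 3881.64
    anemia: 63.60
    thrombocytopenia: 334.78
    nausea: 273.00
    elevated_alt: 1372.98
    decreased_appetite: 273.00
    alopecia: 150.00
    cough: 65.52
    vomiting: 344.93
    upper_respiratory_infection: 1991.14
    hypokalemia: 493.90
    constipation: 71.67
    noninfectious_pneumonia: 1338.40
    diarrhea: 290.65
    febrile_neutropenia: 3881.64
    pancytopenia: 6641.76
  terminal: 1036.80

ae_risks:
  hchop:
    leukopenia: 0.855
    neutropenia: 0.790
    anemia: 0.385
    thrombocytopenia: 0.170
    nausea: 0.230
    elevated_alt: 0.245
    decreased_appetite: 0.160
    alopecia: 0.175
    cough: 0.155
    vomiting: 0.110
    upper_respiratory_infection: 0.095
    hypokalemia: 0.140
    constipation: 0.135
    noninfectious_pneumonia: 0.095
    diarrhea: 0.080
    febrile_neutropenia: 0.025
    pancytopenia: 0.025
  rchop:
    leukopenia: 0.885
    neutropenia: 0.840
    anemia: 0.360
    thrombocytopenia: 0.095
    nausea: 0.245
    elevated_alt: 0.190
    decreased_appetite: 0.210
    alopecia: 0.170
    cough: 0.130
    vomiting: 0.150
    upper_respiratory_infection: 0.145
    hypokalemia: 0.085
    constipation: 0.125
    noninfectious_pneumonia: 0.120
    diarrhea: 0.110
    febrile_neutropenia: 0.030
    pancytopenia: 0.025

utilities:
  pfs: {value: 0.83, lower: 0.66, upper: 1.00}
  pd:  {value: 0.63, lower: 0.50, upper: 0.76}
  ae_disutility: {value: -0.42, lower: -0.50, upper: -0.34}

discount_bounds: {lower: 0.0, upper: 0.08}

regimen:
  n_cycles: 6
  chop:
    - {drug: cyclophosphamide, dose_per_m2: 750}
    - {drug: doxorubicin, dose_per_m2: 50}
    - {drug: vincristine, dose_per_m2: 1.4, cap_mg: 2}
    - {drug: prednisone, mg_per_day: 100, days: 5}
  antibody:
    hchop: {drug: hanlikang, dose_per_m2: 375}
    rchop: {drug: mabthera, dose_per_m2: 375}

# Post-progression pathway cost magnitudes are PLACEHOLDERS: the source
# publication does not print them. They are chosen once so that scenario
# totals follow the qualitative ordering 5 >> 2 > 1 > 4 > 3; replace with
# local tariffs for any substantive use.
scenarios:
  - {id: 1, label: "Transplant-eligible: DHAP + ASCT",
     postprogression_cost: 180000, pd_cycle_cost: 0}
  - {id: 2, label: "Transplant-eligible: novel agent + DHAP + ASCT",
     postprogression_cost: 195000, pd_cycle_cost: 0}
  - {id: 3, label: "Not transplant-eligible: DHAP alone",
     postprogression_cost: 25000, pd_cycle_cost: 0}
  - {id: 4, label: "Not transplant-eligible: novel agents (R2+BTK or Pola-BR)",
     postprogression_cost: 80000, pd_cycle_cost: 0}
  - {id: 5, label: "Primary refractory/early relapse: CAR-T",
     postprogression_cost: 1600000, pd_cycle_cost: 0}

wtp:
  gdp_per_capita: 12358.65
  multipliers: [1, 2, 3]
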