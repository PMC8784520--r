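# Model input registry: metastatic squamous NSCLC, PD-L1 >= 50%,
# US payer perspective, 2021 USD. Monthly model cycle.
histology: squamous
parameters:
  os_theta:  {value: 0.02428, dist: fixed, units: rate, table1: true}
  os_kappa:  {value: 1.27621, dist: fixed, units: shape, table1: true}
  pfs_theta: {value: 0.00985, dist: fixed, units: rate, table1: true}
  pfs_kappa: {value: 2.25359, dist: fixed, units: shape, table1: true}
  hr_os:  {value: 1.13, low: 0.60, high: 2.10, dist: lognormal, units: hazard_ratio, table1: true}
  hr_pfs: {value: 1.06, low: 0.14, high: 1.81, dist: lognormal, units: hazard_ratio, table1: true}
  disc_pembro_mono:  {value: 0.005559, low: 0.002779, high: 0.008338, dist: beta, units: probability, table1: true}
  disc_pembro_combo: {value: 0.011023, low: 0.005512, high: 0.016535, dist: beta, units: probability, table1: true}
  disc_paclitaxel:   {value: 0.010025, low: 0.005013, high: 0.015038, dist: beta, units: probability, table1: true}
  disc_carboplatin:  {value: 0.006890, low: 0.003445, high: 0.010336, dist: beta, units: probability, table1: true}
  price_pembrolizumab:  {value: 52.75, low: 26.38, high: 79.13, dist: gamma, units: usd_per_mg, table1: true}
  price_pemetrexed:     {value: 7.49,  low: 3.75,  high: 11.24, dist: gamma, units: usd_per_mg, table1: true}
  price_paclitaxel:     {value: 0.13,  low: 0.07,  high: 0.20,  dist: gamma, units: usd_per_mg, table1: true}
  price_nab_paclitaxel: {value: 14.08, low: 7.04,  high: 21.12, dist: gamma, units: usd_per_mg, table1: true}
  price_carboplatin:    {value: 0.05,  low: 0.03,  high: 0.08,  dist: gamma, units: usd_per_mg, table1: true}
  price_cisplatin:      {value: 0.18,  low: 0.09,  high: 0.27,  dist: gamma, units: usd_per_mg, table1: true}
  cost_infusion_first_hour: {value: 148.30, low: 74.15, high: 222.45, dist: gamma, units: usd, table1: true}
  cost_infusion_extra_hour: {value: 31.40,  low: 15.70, high: 47.10,  dist: gamma, units: usd, table1: true}
  cost_physician_visit:     {value: 183.19, low: 91.60, high: 274.79, dist: gamma, units: usd, table1: true}
  cost_imaging:             {value: 117.59, low: 58.80, high: 176.39, dist: gamma, units: usd, table1: true}
  cost_bsc:                 {value: 637,    low: 318.50, high: 955.50, dist: gamma, units: usd, table1: true}
  cost_death:               {value: 9433,   low: 4716.50, high: 14149.50, dist: gamma, units: usd, table1: true}
  ae_cost_pembro:       {value: 1400.88, low: 700.44,  high: 2101.31, dist: gamma, units: usd, table1: true}
  ae_cost_pembro_chemo: {value: 5932.63, low: 2966.31, high: 8898.94, dist: gamma, units: usd, table1: true}
  subsq_cost_pembro:       {value: 3785.00, low: 1892.50, high: 5677.50, dist: gamma, units: usd, table1: true}
  subsq_cost_pembro_chemo: {value: 1195.00, low: 597.50,  high: 1792.50, dist: gamma, units: usd, table1: true}
  u_ge12: {value: 0.842, low: 0.823, high: 0.861, dist: beta, units: utility, table1: true}
  u_6_12: {value: 0.814, low: 0.795, high: 0.833, dist: beta, units: utility, table1: true}
  u_1_6:  {value: 0.737, low: 0.717, high: 0.756, dist: beta, units: utility, table1: true}
  u_le1:  {value: 0.568, low: 0.481, high: 0.655, dist: beta, units: utility, table1: true}
  disutility_pembro:       {value: 0.016, low: 0.008, high: 0.024, dist: beta, units: utility, table1: true}
  disutility_pembro_chemo: {value: 0.105, low: 0.053, high: 0.158, dist: beta, units: utility, table1: true}
  bsa:           {value: 1.79, low: 1.78, high: 1.80, dist: normal, units: m2, table1: true}
  crcl:          {value: 70, low: 35.00, high: 105.00, dist: normal, units: ml_per_min, table1: true}
  discount_rate: {value: 3, low: 0, high: 5, dist: normal, units: percent, table1: true}
  subsq_uptake:          {value: 0.5, low: 0.25, high: 0.75, dist: beta, units: probability, table1: false}
  fatal_ae_pembro:       {value: 0, dist: fixed, units: probability, table1: false}
  fatal_ae_pembro_chemo: {value: 0, dist: fixed, units: probability, table1: false}
  start_age:             {value: 64, dist: fixed, units: years, table1: false}
drugs:
  pembrolizumab:  {price_param: price_pembrolizumab, vials: [100], infusion_hours: 0.5}
  paclitaxel:     {price_param: price_paclitaxel, vials: [30, 100, 300], infusion_hours: 3}
  nab_paclitaxel: {price_param: price_nab_paclitaxel, vials: [100], infusion_hours: 0.5}
  carboplatin:    {price_param: price_carboplatin, vials: [50, 150, 450, 600], infusion_hours: 1}
regimens:
  pembro:
    - {drug: pembrolizumab, dose_type: flat, dose: 200, interval_days: 21,
       max_administrations: 35, disc_param: disc_pembro_mono}
  pembro_chemo:
    - {drug: pembrolizumab, dose_type: flat, dose: 200, interval_days: 21,
       max_administrations: 35, disc_param: disc_pembro_combo}
    - {drug: paclitaxel, dose_type: per_m2, dose: 200, interval_days: 21,
       max_administrations: 4, disc_param: disc_paclitaxel}
    - {drug: carboplatin, dose_type: auc, dose: 6, interval_days: 21,
       max_administrations: 4, disc_param: disc_carboplatin}
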