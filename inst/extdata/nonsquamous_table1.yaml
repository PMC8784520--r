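# Model input registry: metastatic non-squamous NSCLC, PD-L1 >= 50%,
# US payer perspective, 2021 USD. Monthly model cycle.
# Each parameter: baseline value, deterministic range (low/high), PSA family.
histology: non_squamous
parameters:
  # log-logistic S(t) = 1 / (1 + theta * t^kappa), t in months, combination arm
  os_theta:  {value: 0.03084, dist: fixed, units: rate, table1: true}
  os_kappa:  {value: 0.92588, dist: fixed, units: shape, table1: true}
  pfs_theta: {value: 0.01422, dist: fixed, units: rate, table1: true}
  pfs_kappa: {value: 1.80138, dist: fixed, units: shape, table1: true}
  # indirect-comparison hazard ratios, pembrolizumab monotherapy vs combination
  hr_os:  {value: 1.67, low: 0.46, high: 2.87, dist: lognormal, units: hazard_ratio, table1: true}
  hr_pfs: {value: 1.53, low: 0.24, high: 2.86, dist: lognormal, units: hazard_ratio, table1: true}
  # per-cycle probabilities of discontinuation due to adverse events
  disc_pembro_mono:  {value: 0.005559, low: 0.002779, high: 0.008338, dist: beta, units: probability, table1: true}
  disc_pembro_combo: {value: 0.010231, low: 0.005115, high: 0.015346, dist: beta, units: probability, table1: true}
  disc_pemetrexed:   {value: 0.011788, low: 0.005894, high: 0.017682, dist: beta, units: probability, table1: true}
  disc_platinum:     {value: 0.003613, low: 0.001807, high: 0.005420, dist: beta, units: probability, table1: true}
  # drug acquisition prices (USD per mg, CMS average sales price)
  price_pembrolizumab:  {value: 52.75, low: 26.38, high: 79.13, dist: gamma, units: usd_per_mg, table1: true}
  price_pemetrexed:     {value: 7.49,  low: 3.75,  high: 11.24, dist: gamma, units: usd_per_mg, table1: true}
  price_paclitaxel:     {value: 0.13,  low: 0.07,  high: 0.20,  dist: gamma, units: usd_per_mg, table1: true}
  price_nab_paclitaxel: {value: 14.08, low: 7.04,  high: 21.12, dist: gamma, units: usd_per_mg, table1: true}
  price_carboplatin:    {value: 0.05,  low: 0.03,  high: 0.08,  dist: gamma, units: usd_per_mg, table1: true}
  price_cisplatin:      {value: 0.18,  low: 0.09,  high: 0.27,  dist: gamma, units: usd_per_mg, table1: true}
  # administration, follow-up and general care costs (USD)
  cost_infusion_first_hour: {value: 148.30, low: 74.15, high: 222.45, dist: gamma, units: usd, table1: true}
  cost_infusion_extra_hour: {value: 31.40,  low: 15.70, high: 47.10,  dist: gamma, units: usd, table1: true}
  cost_physician_visit:     {value: 183.19, low: 91.60, high: 274.79, dist: gamma, units: usd, table1: true}
  cost_imaging:             {value: 117.59, low: 58.80, high: 176.39, dist: gamma, units: usd, table1: true}
  cost_bsc:                 {value: 637,    low: 318.50, high: 955.50, dist: gamma, units: usd, table1: true}
  cost_death:               {value: 9433,   low: 4716.50, high: 14149.50, dist: gamma, units: usd, table1: true}
  # frequency-weighted grade 3+ adverse-event management costs (one-off, USD)
  ae_cost_pembro:       {value: 1400.88, low: 700.44,  high: 2101.31, dist: gamma, units: usd, table1: true}
  ae_cost_pembro_chemo: {value: 6142.07, low: 3071.03, high: 9213.10, dist: gamma, units: usd, table1: true}
  # subsequent anticancer therapy, one-off per progressing patient (USD)
  subsq_cost_pembro:       {value: 12283.00, low: 6141.50, high: 18424.50, dist: gamma, units: usd, table1: true}
  subsq_cost_pembro_chemo: {value: 12831.00, low: 6415.50, high: 19246.50, dist: gamma, units: usd, table1: true}
  # time-to-death utilities
  u_ge12: {value: 0.834, low: 0.823, high: 0.846, dist: beta, units: utility, table1: true}
  u_6_12: {value: 0.765, low: 0.743, high: 0.786, dist: beta, units: utility, table1: true}
  u_1_6:  {value: 0.709, low: 0.690, high: 0.728, dist: beta, units: utility, table1: true}
  u_le1:  {value: 0.563, low: 0.461, high: 0.665, dist: beta, units: utility, table1: true}
  # one-off QALY decrements for grade 3/4 adverse events
  disutility_pembro:       {value: 0.016, low: 0.008, high: 0.024, dist: beta, units: utility, table1: true}
  disutility_pembro_chemo: {value: 0.098, low: 0.049, high: 0.148, dist: beta, units: utility, table1: true}
  # patient and analysis constants
  bsa:           {value: 1.79, low: 1.78, high: 1.80, dist: normal, units: m2, table1: true}
  crcl:          {value: 70, low: 35.00, high: 105.00, dist: normal, units: ml_per_min, table1: true}
  discount_rate: {value: 3, low: 0, high: 5, dist: normal, units: percent, table1: true}
  # reconstruction knobs (standard-of-care defaults, not registry transcriptions)
  subsq_uptake:          {value: 0.5, low: 0.25, high: 0.75, dist: beta, units: probability, table1: false}
  fatal_ae_pembro:       {value: 0, dist: fixed, units: probability, table1: false}
  fatal_ae_pembro_chemo: {value: 0, dist: fixed, units: probability, table1: false}
  start_age:             {value: 64, dist: fixed, units: years, table1: false}
drugs:
  pembrolizumab: {price_param: price_pembrolizumab, vials: [100], infusion_hours: 0.5}
  pemetrexed:    {price_param: price_pemetrexed, vials: [100, 500], infusion_hours: 0.5}
  carboplatin:   {price_param: price_carboplatin, vials: [50, 150, 450, 600], infusion_hours: 1}
  cisplatin:     {price_param: price_cisplatin, vials: [50, 100], infusion_hours: 1}
regimens:
  pembro:
    - {drug: pembrolizumab, dose_type: flat, dose: 200, interval_days: 21,
       max_administrations: 35, disc_param: disc_pembro_mono}
  pembro_chemo:
    - {drug: pembrolizumab, dose_type: flat, dose: 200, interval_days: 21,
       max_administrations: 35, disc_param: disc_pembro_combo}
    - {drug: pemetrexed, dose_type: per_m2, dose: 500, interval_days: 21,
       max_administrations: ~, disc_param: disc_pemetrexed}
    - {drug: carboplatin, dose_type: auc, dose: 5, interval_days: 21,
       max_administrations: 4, disc_param: disc_platinum}
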