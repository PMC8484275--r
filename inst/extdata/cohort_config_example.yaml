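n_visits: 50000
seed: 1
admission_rate: 0.15759999999999999
sex_male_prob:
- 0.47470000000000001
- 0.52969999999999995
age_band_probs:
  .matrix: yes
  dimnames:
  - - discharge
    - admit
  - ~
  data:
  - 0.22839999999999999
  - 0.13969999999999999
  - 0.57469999999999999
  - 0.4269
  - 0.16289999999999999
  - 0.33700000000000002
  - 0.034
  - 0.0964
  nrow: 2
age_band2_beta:
  .matrix: yes
  dimnames:
  - - discharge
    - admit
  - ~
  data:
  - 2.20000000000000018
  - 2.79999999999999982
  - 2.81999999999999984
  - 1.80299999999999994
  nrow: 2
age_band4_mean: 4.75
age_band4_cap: 20.0
child_peds_prob:
- 0.89054
- 0.94850000000000001
child_rest_split:
- 0.94999999999999996
- 0.05
adult_category_probs:
  .matrix: yes
  dimnames:
  - - discharge
    - admit
  - - nontraumatic_adult
    - trauma
    - env_emergency
  data:
  - 0.83609999999999995
  - 0.89876
  - 0.15973000000000001
  - 0.10050000000000001
  - 0.00417
  - 0.00074
  nrow: 2
vital_names:
- temperature
- heart_rate
- respiratory_rate
- systolic_bp
- diastolic_bp
vital_means:
  .matrix: yes
  dimnames:
  - - discharge
    - admit
  - ~
  data:
  - 37.03999999999999915
  - 37.24000000000000199
  - 96.73999999999999488
  - 98.39000000000000057
  - 19.85999999999999943
  - 19.73000000000000043
  - 133.71999999999999886
  - 135.31999999999999318
  - 82.59000000000000341
  - 80.62999999999999545
  nrow: 2
vital_sds:
- 0.59999999999999998
- 18.0
- 2.5
- 22.0
- 14.0
vital_corr:
  .matrix: yes
  dimnames: ~
  data:
  - 1.0
  - 0.29999999999999999
  - 0.20000000000000001
  - 0.05
  - 0.05
  - 0.29999999999999999
  - 1.0
  - 0.29999999999999999
  - 0.10000000000000001
  - 0.14999999999999999
  - 0.20000000000000001
  - 0.29999999999999999
  - 1.0
  - 0.05
  - 0.05
  - 0.05
  - 0.10000000000000001
  - 0.05
  - 1.0
  - 0.65000000000000002
  - 0.05
  - 0.14999999999999999
  - 0.05
  - 0.65000000000000002
  - 1.0
  nrow: 5
vital_bounds:
  .matrix: yes
  dimnames:
  - - lower
    - upper
  - ~
  data:
  - 34.0
  - 42.5
  - 30.0
  - 220.0
  - 6.0
  - 60.0
  - 60.0
  - 260.0
  - 30.0
  - 160.0
  nrow: 2
map_noise:
  values:
  - -2
  - -1
  - 0
  - 1
  probs:
  - 0.16666666666666666
  - 0.16666666666666666
  - 0.5
  - 0.16666666666666666
history_has_prob:
- 0.15040000000000001
- 0.47010000000000002
history_lambda:
- 0.74099999999999999
- 0.86799999999999999
cc_catalogue:
  .data_frame: yes
  columns:
    code:
    - NTA01
    - NTA02
    - NTA03
    - NTA04
    - NTA05
    - NTA06
    - NTA07
    - NTA08
    - NTA09
    - NTA10
    - NTA11
    - NTA12
    - NTA13
    - NTA14
    - NTA15
    - NTA16
    - NTA17
    - NTA18
    - NTA19
    - NTA20
    - NTA21
    - NTA22
    - NTA23
    - NTA24
    - NTA25
    - PED01
    - PED02
    - PED03
    - PED04
    - PED05
    - PED06
    - PED07
    - PED08
    - TRA01
    - TRA02
    - TRA03
    - TRA04
    - TRA05
    - TRA06
    - ENV01
    category:
    - nontraumatic_adult
    - nontraumatic_adult
    - nontraumatic_adult
    - nontraumatic_adult
    - nontraumatic_adult
    - nontraumatic_adult
    - nontraumatic_adult
    - nontraumatic_adult
    - nontraumatic_adult
    - nontraumatic_adult
    - nontraumatic_adult
    - nontraumatic_adult
    - nontraumatic_adult
    - nontraumatic_adult
    - nontraumatic_adult
    - nontraumatic_adult
    - nontraumatic_adult
    - nontraumatic_adult
    - nontraumatic_adult
    - nontraumatic_adult
    - nontraumatic_adult
    - nontraumatic_adult
    - nontraumatic_adult
    - nontraumatic_adult
    - nontraumatic_adult
    - pediatrics
    - pediatrics
    - pediatrics
    - pediatrics
    - pediatrics
    - pediatrics
    - pediatrics
    - pediatrics
    - trauma
    - trauma
    - trauma
    - trauma
    - trauma
    - trauma
    - env_emergency
    weight:
    - 100.0
    - 80.0
    - 65.0
    - 55.0
    - 48.0
    - 42.0
    - 36.0
    - 31.0
    - 27.0
    - 23.0
    - 20.0
    - 17.0
    - 15.0
    - 13.0
    - 11.0
    - 10.0
    - 8.0
    - 7.0
    - 6.0
    - 5.0
    - 4.0
    - 4.0
    - 3.0
    - 3.0
    - 2.0
    - 50.0
    - 35.0
    - 25.0
    - 18.0
    - 12.0
    - 8.0
    - 5.0
    - 3.0
    - 60.0
    - 40.0
    - 25.0
    - 15.0
    - 8.0
    - 4.0
    - 1.0
    enrichment:
    - 0.38200000000000001
    - 0.52800000000000002
    - 0.66500000000000004
    - 0.83699999999999997
    - 1.0
    - 1.15700000000000003
    - 0.57399999999999995
    - 1.45599999999999996
    - 1.7410000000000001
    - 0.752
    - 2.08099999999999996
    - 1.0
    - 2.53600000000000003
    - 0.91900000000000004
    - 3.03100000000000014
    - 1.30899999999999994
    - 3.62400000000000011
    - 0.66500000000000004
    - 4.19299999999999962
    - 1.60000000000000009
    - 5.27799999999999958
    - 1.879
    - 2.40799999999999992
    - 1.07899999999999996
    - 4.74300000000000033
    - 0.57399999999999995
    - 0.752
    - 1.0
    - 1.30899999999999994
    - 0.66500000000000004
    - 1.7410000000000001
    - 2.27899999999999991
    - 3.03100000000000014
    - 0.47999999999999998
    - 0.752
    - 1.07899999999999996
    - 1.60000000000000009
    - 2.40799999999999992
    - 3.62400000000000011
    - 1.0
    mortality:
    - 0.003
    - 0.005
    - 0.006
    - 0.009
    - 0.012
    - 0.015
    - 0.006
    - 0.018
    - 0.027
    - 0.009
    - 0.036
    - 0.012
    - 0.048
    - 0.012
    - 0.06
    - 0.018
    - 0.07199999999999999
    - 0.007
    - 0.09
    - 0.024
    - 0.12
    - 0.03
    - 0.042
    - 0.015
    - 0.108
    - 0.001
    - 0.001
    - 0.002
    - 0.003
    - 0.001
    - 0.005
    - 0.007
    - 0.012
    - 0.001
    - 0.002
    - 0.005
    - 0.012
    - 0.03
    - 0.06
    - 0.08
rate_missing_fields: 0.03
rate_non_standard_disposition: 0.02
rate_other_level: 0.29999999999999999
visits_per_patient: 1.57000000000000006
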