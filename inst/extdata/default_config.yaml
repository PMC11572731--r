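n_ba: 117.0
n_wa: 123.0
mode: linear
covariates:
  age:
    mean:
      ba: 44.54999999999999716
      wa: 43.0
    sd:
      ba: 12.08999999999999986
      wa: 10.58000000000000007
    min: 18.0
  male_frac:
    ba: 0.23899999999999999
    wa: 0.309
  duration:
    mean:
      ba: 11.0
      wa: 10.59999999999999964
    sd:
      ba: 7.51999999999999957
      wa: 8.30000000000000071
    min: 0.0
  dmt:
    ba:
      higher: 0.50429999999999997
      lower: 0.32440000000000002
      untreated: 0.17130000000000001
    wa:
      higher: 0.52029999999999998
      lower: 0.33329999999999999
      untreated: 0.1464
  income:
    mean:
      ba: 66085.80999999999767169
      wa: 120000.0
    sd:
      ba: 29486.83000000000174623
      wa: 40388.69000000000232831
    min: 1000.0
  non_prl_volume:
    mean:
      ba: 8029.3000000000001819
      wa: 3600.0
    sd:
      ba: 9336.09000000000014552
      wa: 5778.23999999999978172
  prl_lesion_volume:
    mean: 750.0
    sd: 400.0
  flair:
    mu:
      ba: 23.82999999999999829
      wa: 22.0
    size:
      ba: 1.39339999999999997
      wa: 1.23940000000000006
mediator:
  intercept: 1.59049211161352821
  race: 4.65000000000000036
  age: 0.05
  dmt_lower: -1.5
  dmt_untreated: 1.0
  sd:
    ba: 15.25
    wa: 7.5
  mean_wa: 3.39999999999999991
outcome:
  intercept: -0.87575988838647167
  race: 0.59999999999999998
  mediator: 0.021
  age: 0.05
  dmt_lower: -0.57999999999999996
  dmt_untreated: -0.31
  non_prl_volume: 5.00000000000000024e-05
  sd:
    ba: 1.91999999999999993
    wa: 1.46999999999999997
  mean_wa: 1.30000000000000004
count:
  logit_intercept: -3.68390100000000009
  logit_race: 0.64655399999999996
  overdispersion_sd:
    ba: 1.26180300000000001
    wa: 0.86241699999999999
confounder_strength: 0.0
round_edss: no
seed: 1.0
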