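version: heartage-coefficients 1.0 refit-r20090701
models:
- algorithm: FULL
  sex: male
  terms:
  - name: age
    transform: log
    coefficient: 3.06117000000000017
  - name: tc
    transform: log
    coefficient: 1.12369999999999992
  - name: hdl
    transform: log
    coefficient: -0.93262999999999996
  - name: sbp
    transform: log
    coefficient: 1.93303000000000003
    treated: no
  - name: sbp
    transform: log
    coefficient: 1.99880999999999998
    treated: yes
  - name: smoker
    transform: indicator
    coefficient: 0.65451000000000004
  - name: diabetic
    transform: indicator
    coefficient: 0.57367000000000001
  mean_linear_predictor: 23.98019999999999996
  baseline_survival_10y: 0.88936000000000004
- algorithm: FULL
  sex: female
  terms:
  - name: age
    transform: log
    coefficient: 2.32887999999999984
  - name: tc
    transform: log
    coefficient: 1.20903999999999989
  - name: hdl
    transform: log
    coefficient: -0.70833000000000002
  - name: sbp
    transform: log
    coefficient: 2.76156999999999986
    treated: no
  - name: sbp
    transform: log
    coefficient: 2.82263000000000019
    treated: yes
  - name: smoker
    transform: indicator
    coefficient: 0.52873000000000003
  - name: diabetic
    transform: indicator
    coefficient: 0.69154000000000004
  mean_linear_predictor: 26.19310000000000116
  baseline_survival_10y: 0.95011999999999996
- algorithm: ALT4_SBP_BMI
  sex: male
  terms:
  - name: age
    transform: log
    coefficient: 3.11296000000000017
  - name: bmi
    transform: log
    coefficient: 0.79276999999999997
  - name: sbp
    transform: log
    coefficient: 1.85508000000000006
    treated: no
  - name: sbp
    transform: log
    coefficient: 1.92671999999999999
    treated: yes
  - name: smoker
    transform: indicator
    coefficient: 0.70952999999999999
  - name: diabetic
    transform: indicator
    coefficient: 0.53159999999999996
  mean_linear_predictor: 23.93880000000000052
  baseline_survival_10y: 0.88431000000000004
- algorithm: ALT4_SBP_BMI
  sex: female
  terms:
  - name: age
    transform: log
    coefficient: 2.7210700000000001
  - name: bmi
    transform: log
    coefficient: 0.51124999999999998
  - name: sbp
    transform: log
    coefficient: 2.81291000000000002
    treated: no
  - name: sbp
    transform: log
    coefficient: 2.88267000000000007
    treated: yes
  - name: smoker
    transform: indicator
    coefficient: 0.61868000000000001
  - name: diabetic
    transform: indicator
    coefficient: 0.77763000000000004
  mean_linear_predictor: 26.01450000000000173
  baseline_survival_10y: 0.94833000000000001
- algorithm: ALT1_TC_HDL
  sex: male
  terms:
  - name: age
    transform: log
    coefficient: 3.40131000000000006
  - name: tc
    transform: log
    coefficient: 1.24909000000000003
  - name: hdl
    transform: log
    coefficient: -0.95801999999999998
  - name: smoker
    transform: indicator
    coefficient: 0.63985999999999998
  - name: diabetic
    transform: indicator
    coefficient: 0.60855999999999999
  mean_linear_predictor: 16.3907999999999987
  baseline_survival_10y: 0.91486000000000001
- algorithm: ALT2_TC_SBP_BMI
  sex: male
  terms:
  - name: age
    transform: log
    coefficient: 2.99320999999999993
  - name: tc
    transform: log
    coefficient: 1.18589999999999995
  - name: sbp
    transform: log
    coefficient: 1.82851999999999992
    treated: no
  - name: sbp
    transform: log
    coefficient: 1.89559000000000011
    treated: yes
  - name: bmi
    transform: log
    coefficient: 0.46578999999999998
  - name: smoker
    transform: indicator
    coefficient: 0.64507999999999999
  - name: diabetic
    transform: indicator
    coefficient: 0.60341
  mean_linear_predictor: 28.45530000000000115
  baseline_survival_10y: 0.91557999999999995
- algorithm: ALT3_TC_BMI
  sex: male
  terms:
  - name: age
    transform: log
    coefficient: 3.33041000000000009
  - name: tc
    transform: log
    coefficient: 1.26175999999999999
  - name: bmi
    transform: log
    coefficient: 0.78232000000000002
  - name: smoker
    transform: indicator
    coefficient: 0.63793999999999995
  - name: diabetic
    transform: indicator
    coefficient: 0.58757999999999999
  mean_linear_predictor: 22.37369999999999948
  baseline_survival_10y: 0.91354000000000002
- algorithm: ALT5_BMI
  sex: male
  terms:
  - name: age
    transform: log
    coefficient: 3.4652400000000001
  - name: bmi
    transform: log
    coefficient: 1.01855000000000007
  - name: smoker
    transform: indicator
    coefficient: 0.63334000000000001
  - name: diabetic
    transform: indicator
    coefficient: 0.57684000000000002
  mean_linear_predictor: 17.0558000000000014
  baseline_survival_10y: 0.91080000000000005
- algorithm: ALT1_TC_HDL
  sex: female
  terms:
  - name: age
    transform: log
    coefficient: 2.86988999999999983
  - name: tc
    transform: log
    coefficient: 1.39111999999999991
  - name: hdl
    transform: log
    coefficient: -0.74309999999999998
  - name: smoker
    transform: indicator
    coefficient: 0.53095999999999999
  - name: diabetic
    transform: indicator
    coefficient: 0.67952999999999997
  mean_linear_predictor: 15.75130000000000052
  baseline_survival_10y: 0.95940999999999999
- algorithm: ALT2_TC_SBP_BMI
  sex: female
  terms:
  - name: age
    transform: log
    coefficient: 2.30934000000000017
  - name: tc
    transform: log
    coefficient: 1.26019999999999999
  - name: sbp
    transform: log
    coefficient: 2.8058200000000002
    treated: no
  - name: sbp
    transform: log
    coefficient: 2.86870000000000003
    treated: yes
  - name: bmi
    transform: log
    coefficient: 0.32085000000000002
  - name: smoker
    transform: indicator
    coefficient: 0.53417000000000003
  - name: diabetic
    transform: indicator
    coefficient: 0.66578999999999999
  mean_linear_predictor: 30.34740000000000038
  baseline_survival_10y: 0.96113999999999999
- algorithm: ALT3_TC_BMI
  sex: female
  terms:
  - name: age
    transform: log
    coefficient: 2.80995000000000017
  - name: tc
    transform: log
    coefficient: 1.38257000000000008
  - name: bmi
    transform: log
    coefficient: 0.78242
  - name: smoker
    transform: indicator
    coefficient: 0.53027999999999997
  - name: diabetic
    transform: indicator
    coefficient: 0.65820999999999996
  mean_linear_predictor: 20.97990000000000066
  baseline_survival_10y: 0.95904999999999996
- algorithm: ALT5_BMI
  sex: female
  terms:
  - name: age
    transform: log
    coefficient: 2.96262999999999987
  - name: bmi
    transform: log
    coefficient: 1.02715000000000001
  - name: smoker
    transform: indicator
    coefficient: 0.53061000000000003
  - name: diabetic
    transform: indicator
    coefficient: 0.65437999999999996
  mean_linear_predictor: 15.09190000000000076
  baseline_survival_10y: 0.95743999999999996
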