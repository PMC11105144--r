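name: amc2020
n_subjects: 9623
race_probs:
  White: 0.416294294918425
  Asian: 0.123662059648758
  Black: 0.0906162319443
  Other: 0.222383871973397
  Unknown: 0.14704354151512
target_prevalence: 0.146
target_rate_ratio: 0.637
proxy_strength: 0.8
seed: 1
feature_spec:
- name: hx_depression
  category: mental_health
  type: binary
  baseline: 0.12
  beta: 5.06
  proxy_dir: -1.0
- name: hx_anxiety
  category: mental_health
  type: binary
  baseline: 0.15
  beta: 3.68
  proxy_dir: -1.0
- name: hx_mood_disorder
  category: mental_health
  type: binary
  baseline: 0.06
  beta: 4.14
  proxy_dir: 0.0
- name: hx_prior_ppd
  category: mental_health
  type: binary
  baseline: 0.04
  beta: 5.98
  proxy_dir: 0.0
- name: hx_psychotherapy
  category: mental_health
  type: binary
  baseline: 0.1
  beta: 2.76
  proxy_dir: -1.0
- name: hx_substance_use
  category: mental_health
  type: binary
  baseline: 0.03
  beta: 2.3
  proxy_dir: 0.0
- name: cm_diabetes
  category: comorbidity
  type: binary
  baseline: 0.08
  beta: 0.92
  proxy_dir: 0.0
- name: cm_hypertension
  category: comorbidity
  type: binary
  baseline: 0.1
  beta: 0.92
  proxy_dir: 1.0
- name: cm_thyroid_disorder
  category: comorbidity
  type: binary
  baseline: 0.07
  beta: 0.69
  proxy_dir: 0.0
- name: cm_obesity
  category: comorbidity
  type: binary
  baseline: 0.2
  beta: 0.69
  proxy_dir: 1.0
- name: cm_anemia
  category: comorbidity
  type: binary
  baseline: 0.18
  beta: 0.46
  proxy_dir: 1.0
- name: cm_migraine
  category: comorbidity
  type: binary
  baseline: 0.09
  beta: 0.92
  proxy_dir: 0.0
- name: cm_autoimmune
  category: comorbidity
  type: binary
  baseline: 0.03
  beta: 0.69
  proxy_dir: 0.0
- name: ob_cesarean
  category: obstetric
  type: binary
  baseline: 0.3
  beta: 0.92
  proxy_dir: 0.0
- name: ob_preterm_birth
  category: obstetric
  type: binary
  baseline: 0.09
  beta: 1.38
  proxy_dir: 0.0
- name: ob_preeclampsia
  category: obstetric
  type: binary
  baseline: 0.05
  beta: 1.61
  proxy_dir: 0.0
- name: ob_multiple_gest
  category: obstetric
  type: binary
  baseline: 0.03
  beta: 1.15
  proxy_dir: 0.0
- name: ob_nicu_admission
  category: obstetric
  type: binary
  baseline: 0.08
  beta: 1.15
  proxy_dir: 0.0
- name: ob_labor_complic
  category: obstetric
  type: binary
  baseline: 0.15
  beta: 0.92
  proxy_dir: 0.0
- name: rx_ssri
  category: medication
  type: binary
  baseline: 0.08
  beta: 4.14
  proxy_dir: -1.0
- name: rx_benzodiazepine
  category: medication
  type: binary
  baseline: 0.04
  beta: 2.76
  proxy_dir: 0.0
- name: rx_opioid
  category: medication
  type: binary
  baseline: 0.12
  beta: 1.15
  proxy_dir: 0.0
- name: rx_antiemetic
  category: medication
  type: binary
  baseline: 0.25
  beta: 0.69
  proxy_dir: 0.0
- name: rx_insulin
  category: medication
  type: binary
  baseline: 0.04
  beta: 0.92
  proxy_dir: 0.0
- name: rx_antihypertensive
  category: medication
  type: binary
  baseline: 0.06
  beta: 0.92
  proxy_dir: 0.0
- name: age_std
  category: demographic
  type: continuous
  baseline: 0.0
  beta: 0.81
  proxy_dir: 0.0
- name: bmi_std
  category: demographic
  type: continuous
  baseline: 0.0
  beta: 0.58
  proxy_dir: 0.0
- name: parity_std
  category: demographic
  type: continuous
  baseline: 0.0
  beta: 0.46
  proxy_dir: 0.0
- name: prenatal_visits_std
  category: demographic
  type: continuous
  baseline: 0.0
  beta: 0.69
  proxy_dir: -1.0
- name: area_deprivation_std
  category: demographic
  type: continuous
  baseline: 0.0
  beta: 0.58
  proxy_dir: 1.0
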