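# Minimal block-structure configuration (schema version 1).
# blocks: ordered life stages; each lists its endogenous (continuous
# responses, usable as covariates later) and exogenous (covariate-only)
# variables. variables: type per variable (continuous | binary |
# categorical with levels); forced covariates enter every regression
# without selection; no_impute drops rows missing that variable.
schema_version: 1
blocks:
  - name: prenatal_birth
    endogenous: [bw]
    exogenous: [sex, matBMI, matSmoke]
  - name: childhood
    endogenous: [bmiAR]
    exogenous: []
  - name: midlife
    endogenous: [bmi46]
    exogenous: [sep46]
variables:
  sex: {type: binary, forced: true}
  matBMI: {type: continuous}
  matSmoke: {type: binary}
  bw: {type: continuous}
  bmiAR: {type: continuous}
  sep46: {type: continuous}
  bmi46: {type: continuous}
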