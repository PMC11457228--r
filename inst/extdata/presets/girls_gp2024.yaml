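# Packaged girls cohort preset: template calibrated to the cohort-mean spurt
# parameters; random-effect and noise scales chosen to match the reported
# dispersion and fit error of the study population.
sex: female
age_pivot: 11.5
noise_sd: 0.714
template:
  h7: 121.8
  targets:
    aogs: 8.57
    ogsv: 5.10
    aphv: 10.99
    phv: 8.32
    gsi: 3.72
random_effects:
  sds:
    size: 5.0
    tempo: 0.74
    velocity: 0.130
  correlation:
    - [1.00, 0.18, 0.29]
    - [0.18, 1.00, -0.36]
    - [0.29, -0.36, 1.00]
schedule:
  from: 7.25
  to: 16.25
  by: 0.5
  jitter: 0.25
  miss_prob: 0.31
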