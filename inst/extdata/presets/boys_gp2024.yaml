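# Packaged boys cohort preset: template calibrated to the cohort-mean spurt
# parameters; random-effect and noise scales chosen to match the reported
# dispersion and fit error of the study population.
sex: male
age_pivot: 11.5
noise_sd: 0.78
template:
  h7: 122.9
  targets:
    aogs: 10.17
    ogsv: 5.43
    aphv: 12.46
    phv: 9.61
    gsi: 3.58
random_effects:
  sds:
    size: 5.0
    tempo: 0.69
    velocity: 0.131
  correlation:
    - [1.00, 0.09, 0.33]
    - [0.09, 1.00, -0.43]
    - [0.33, -0.43, 1.00]
schedule:
  from: 7.25
  to: 16.25
  by: 0.5
  jitter: 0.25
  miss_prob: 0.31
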