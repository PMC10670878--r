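# Demonstration pipeline: simulate each data modality, then run every
# analysis on it. Run from the package root with
#   Rscript inst/scripts/sporoquant.R inst/extdata/demo_pipeline.yaml --out demo_out
seed: 1
output_dir: demo_out
stages:
  - stage: simulate-images
    name: field
    params:
      image_shape: [192, 192]
      n_sporangia: 3
  - stage: segment
    name: seg
    input: field
    high_quantile: 0.995
    low_quantile: 0.95
    min_area: 20
    max_distance: 3.0
    max_angle: 30.0
  - stage: ratio
    name: ratios
    input: field
    high_quantile: 0.995
    low_quantile: 0.95
  - stage: simulate-frap
    name: frap_sim
    params:
      k: 0.01
      bleach_target: forespore
  - stage: frap
    name: frap
    input: frap_sim
    v_fs: 0.35
    v_mc: 3.0
  - stage: simulate-frap
    name: flip_sim
    params:
      k: 0.01
      bleach_target: mother_cell
  - stage: flip
    name: flip
    input: flip_sim
  - stage: simulate-peptides
    name: peptides_mc
    params:
      scenario: mc_transporter
  - stage: simulate-peptides
    name: peptides_ctl
    params:
      scenario: control
  - stage: silac
    name: silac
    peptides: peptides_mc
    regulons: peptides_mc_regulons
    control: peptides_ctl
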