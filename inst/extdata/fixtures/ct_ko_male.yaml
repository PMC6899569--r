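# Synthetic cortex phantom: knockout male composition — few large
# elongated canals, many small lacunae (bimodal lacunar volumes).
# Ground-truth pore partition targets 22.3% lacunar / 76.1% canal,
# renormalised over the two generated classes (22.66 / 77.34).
outer_radius_um: 127
inner_radius_um: 55
length_slices: 300
voxel_size_um: 0.65
lacunae:
  count: 900
  meanlog: 5.7038    # log(300 um^3), the wild-type-like mode
  sdlog: 0.35
  mode2_weight: 0.55 # small-volume population
  mode2_meanlog: 4.4998   # log(90 um^3)
  mode2_sdlog: 0.35
  min_volume_um3: 40
  max_volume_um3: 2000
  max_elongation: 2.2
canals:
  radius_um: 6.5
  length_um: 110
  length_jitter: 0.15
  orientation_sd_deg: 4
  target_canal_ratio: 3.4125561   # 76.1 / 22.3
intensity:
  bone_mean: 180
  background_mean: 40
  noise_sd: 5
  bit_depth: 8
osteoid:
  enabled: false
seed: 20303
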