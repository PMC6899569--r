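# Synthetic cortex phantom: wild-type female composition.
# Ground-truth pore partition targets 75.8% lacunar / 22.0% canal,
# renormalised over the two generated classes (77.50 / 22.50).
outer_radius_um: 127
inner_radius_um: 55
length_slices: 300
voxel_size_um: 0.65
lacunae:
  count: 1200
  meanlog: 5.5215    # log(250 um^3)
  sdlog: 0.45
  min_volume_um3: 60
  max_volume_um3: 2000
  max_elongation: 2.2
canals:
  radius_um: 4.0
  length_um: 90
  length_jitter: 0.15
  orientation_sd_deg: 4
  target_canal_ratio: 0.2902375   # 22.0 / 75.8
intensity:
  bone_mean: 180
  background_mean: 40
  noise_sd: 5
  bit_depth: 8
osteoid:
  enabled: false
seed: 20101
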