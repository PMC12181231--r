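# Example pipeline configuration (desk scale).
# Scene defaults emulate a 3 mm x 1.5 mm field of view at ~0.26 px/um;
# this example is scaled down so the full pipeline runs in minutes on one CPU.
seed: 1

scene:
  image_height: 128
  image_width: 128
  droplet_radius: 11
  radius_jitter: 0.08
  droplets_per_frame: 5
  crystal_size_px: 3
  background_contrast: 0.5
  noise_sd: 5

kinetics:
  k_true: 0.027            # 1/min
  labile_fraction: 0.1
  p_vaterite: 0.5
  timesteps: [0, 22.5, 45, 67.5, 90, 112.5, 135, 157.5, 180,
              202.5, 225, 247.5, 270, 292.5, 315, 337.5, 360]
  n_locations: 4
  per_location_time_offset_min: 1.5

unet:
  droplet:  {n_encoders: 3, base_filters: 8, learning_rate: 0.002,
             batch_size: 4, n_epochs: 40}
  vaterite: {n_encoders: 3, base_filters: 8, learning_rate: 0.002,
             batch_size: 4, n_epochs: 80}
  calcite:  {n_encoders: 3, base_filters: 8, learning_rate: 0.002,
             batch_size: 4, n_epochs: 80}

train:
  split_fraction: 0.8
  hflip: true
  vflip: true
  rot90: true
  brightness_jitter: 0.05
  loss_mode: sum

tiling:
  grid: [1, 1]
  target_hw: [64, 64]

counting:
  min_area_droplet: 50
  min_area_crystal: 1
  connectivity: 8
  kmeans_seed: 0

detection:
  margin_px: 2

kinetics_options:
  bootstrap: true
  n_boot: 200
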