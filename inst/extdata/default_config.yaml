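seed: 20210121
classes:
- name: background
  t1_mean: 2000.0
  t1_sd: 0.0
  t1_min: 2000.0
  t1_max: 2000.0
  t2s_mean: 40.0
  t2s_sd: 0.0
  t2s_min: 40.0
  t2s_max: 40.0
  m0_mean: 0.05
  m0_sd: 0.0
- name: fibrous
  t1_mean: 836.18
  t1_sd: 322.36
  t1_min: 239.36
  t1_max: 1970.11
  t2s_mean: 13.23
  t2s_sd: 7.14
  t2s_min: 2.04
  t2s_max: 71.64
  m0_mean: 1.0
  m0_sd: 0.05
- name: lipid
  t1_mean: 994.98
  t1_sd: 338.93
  t1_min: 241.03
  t1_max: 2290.56
  t2s_mean: 11.38
  t2s_sd: 5.17
  t2s_min: 3.59
  t2s_max: 31.0
  m0_mean: 1.0
  m0_sd: 0.05
- name: inflammation
  t1_mean: 1317.74
  t1_sd: 555.95
  t1_min: 317.14
  t1_max: 2670.81
  t2s_mean: 11.35
  t2s_sd: 11.26
  t2s_min: 1.14
  t2s_max: 68.15
  m0_mean: 1.0
  m0_sd: 0.05
- name: hemorrhage
  t1_mean: 1393.45
  t1_sd: 774.46
  t1_min: 406.08
  t1_max: 3560.94
  t2s_mean: 8.1
  t2s_sd: 3.77
  t2s_min: 1.55
  t2s_max: 28.98
  m0_mean: 1.0
  m0_sd: 0.05
plaques:
- plaque_id: plaque01
  grid_shape:
  - 8
  - 36
  - 36
  voxel_size_um:
  - 120.0
  - 120.0
  - 120.0
  regions:
  - shape: ellipsoid
    label: fibrous
    center:
    - 4.5
    - 18.5
    - 18.5
    radii:
    - 3.5
    - 16.5
    - 16.5
  - shape: ellipsoid
    label: lipid
    center:
    - 4.5
    - 18.5
    - 8.0
    radii:
    - 2.5
    - 9.0
    - 4.5
  - shape: ellipsoid
    label: inflammation
    center:
    - 4.5
    - 18.5
    - 18.0
    radii:
    - 2.5
    - 9.0
    - 4.5
  - shape: ellipsoid
    label: hemorrhage
    center:
    - 4.5
    - 18.5
    - 28.0
    radii:
    - 2.5
    - 9.0
    - 4.5
  background_class: background
- plaque_id: plaque02
  grid_shape:
  - 8
  - 36
  - 36
  voxel_size_um:
  - 120.0
  - 120.0
  - 120.0
  regions:
  - shape: ellipsoid
    label: fibrous
    center:
    - 4.5
    - 18.5
    - 18.5
    radii:
    - 3.5
    - 16.5
    - 16.5
  - shape: ellipsoid
    label: lipid
    center:
    - 4.5
    - 18.5
    - 8.0
    radii:
    - 2.5
    - 9.0
    - 4.5
  - shape: ellipsoid
    label: inflammation
    center:
    - 4.5
    - 18.5
    - 18.0
    radii:
    - 2.5
    - 9.0
    - 4.5
  - shape: ellipsoid
    label: hemorrhage
    center:
    - 4.5
    - 18.5
    - 28.0
    radii:
    - 2.5
    - 9.0
    - 4.5
  background_class: background
- plaque_id: plaque03
  grid_shape:
  - 8
  - 36
  - 36
  voxel_size_um:
  - 120.0
  - 120.0
  - 120.0
  regions:
  - shape: ellipsoid
    label: fibrous
    center:
    - 4.5
    - 18.5
    - 18.5
    radii:
    - 3.5
    - 16.5
    - 16.5
  - shape: ellipsoid
    label: lipid
    center:
    - 4.5
    - 18.5
    - 8.0
    radii:
    - 2.5
    - 9.0
    - 4.5
  - shape: ellipsoid
    label: inflammation
    center:
    - 4.5
    - 18.5
    - 18.0
    radii:
    - 2.5
    - 9.0
    - 4.5
  - shape: ellipsoid
    label: hemorrhage
    center:
    - 4.5
    - 18.5
    - 28.0
    radii:
    - 2.5
    - 9.0
    - 4.5
  background_class: background
- plaque_id: plaque04
  grid_shape:
  - 8
  - 36
  - 36
  voxel_size_um:
  - 120.0
  - 120.0
  - 120.0
  regions:
  - shape: ellipsoid
    label: fibrous
    center:
    - 4.5
    - 18.5
    - 18.5
    radii:
    - 3.5
    - 16.5
    - 16.5
  - shape: ellipsoid
    label: lipid
    center:
    - 4.5
    - 18.5
    - 8.0
    radii:
    - 2.5
    - 9.0
    - 4.5
  - shape: ellipsoid
    label: inflammation
    center:
    - 4.5
    - 18.5
    - 18.0
    radii:
    - 2.5
    - 9.0
    - 4.5
  - shape: ellipsoid
    label: hemorrhage
    center:
    - 4.5
    - 18.5
    - 28.0
    radii:
    - 2.5
    - 9.0
    - 4.5
  background_class: background
- plaque_id: plaque05
  grid_shape:
  - 8
  - 36
  - 36
  voxel_size_um:
  - 120.0
  - 120.0
  - 120.0
  regions:
  - shape: ellipsoid
    label: fibrous
    center:
    - 4.5
    - 18.5
    - 18.5
    radii:
    - 3.5
    - 16.5
    - 16.5
  - shape: ellipsoid
    label: lipid
    center:
    - 4.5
    - 18.5
    - 8.0
    radii:
    - 2.5
    - 9.0
    - 4.5
  - shape: ellipsoid
    label: inflammation
    center:
    - 4.5
    - 18.5
    - 18.0
    radii:
    - 2.5
    - 9.0
    - 4.5
  - shape: ellipsoid
    label: hemorrhage
    center:
    - 4.5
    - 18.5
    - 28.0
    radii:
    - 2.5
    - 9.0
    - 4.5
  background_class: background
- plaque_id: plaque06
  grid_shape:
  - 8
  - 36
  - 36
  voxel_size_um:
  - 120.0
  - 120.0
  - 120.0
  regions:
  - shape: ellipsoid
    label: fibrous
    center:
    - 4.5
    - 18.5
    - 18.5
    radii:
    - 3.5
    - 16.5
    - 16.5
  - shape: ellipsoid
    label: lipid
    center:
    - 4.5
    - 18.5
    - 10.5
    radii:
    - 2.5
    - 9.0
    - 7.0
  - shape: ellipsoid
    label: inflammation
    center:
    - 4.5
    - 18.5
    - 25.5
    radii:
    - 2.5
    - 9.0
    - 7.0
  background_class: background
- plaque_id: plaque07
  grid_shape:
  - 8
  - 36
  - 36
  voxel_size_um:
  - 120.0
  - 120.0
  - 120.0
  regions:
  - shape: ellipsoid
    label: fibrous
    center:
    - 4.5
    - 18.5
    - 18.5
    radii:
    - 3.5
    - 16.5
    - 16.5
  - shape: ellipsoid
    label: lipid
    center:
    - 4.5
    - 18.5
    - 10.5
    radii:
    - 2.5
    - 9.0
    - 7.0
  - shape: ellipsoid
    label: inflammation
    center:
    - 4.5
    - 18.5
    - 25.5
    radii:
    - 2.5
    - 9.0
    - 7.0
  background_class: background
- plaque_id: plaque08
  grid_shape:
  - 8
  - 36
  - 36
  voxel_size_um:
  - 120.0
  - 120.0
  - 120.0
  regions:
  - shape: ellipsoid
    label: fibrous
    center:
    - 4.5
    - 18.5
    - 18.5
    radii:
    - 3.5
    - 16.5
    - 16.5
  - shape: ellipsoid
    label: lipid
    center:
    - 4.5
    - 18.5
    - 10.5
    radii:
    - 2.5
    - 9.0
    - 7.0
  - shape: ellipsoid
    label: inflammation
    center:
    - 4.5
    - 18.5
    - 25.5
    radii:
    - 2.5
    - 9.0
    - 7.0
  background_class: background
- plaque_id: plaque09
  grid_shape:
  - 8
  - 36
  - 36
  voxel_size_um:
  - 120.0
  - 120.0
  - 120.0
  regions:
  - shape: ellipsoid
    label: fibrous
    center:
    - 4.5
    - 18.5
    - 18.5
    radii:
    - 3.5
    - 16.5
    - 16.5
  - shape: ellipsoid
    label: lipid
    center:
    - 4.5
    - 18.5
    - 10.5
    radii:
    - 2.5
    - 9.0
    - 7.0
  - shape: ellipsoid
    label: inflammation
    center:
    - 4.5
    - 18.5
    - 25.5
    radii:
    - 2.5
    - 9.0
    - 7.0
  background_class: background
- plaque_id: plaque10
  grid_shape:
  - 8
  - 36
  - 36
  voxel_size_um:
  - 120.0
  - 120.0
  - 120.0
  regions:
  - shape: ellipsoid
    label: fibrous
    center:
    - 4.5
    - 18.5
    - 18.5
    radii:
    - 3.5
    - 16.5
    - 16.5
  - shape: ellipsoid
    label: lipid
    center:
    - 4.5
    - 18.5
    - 18.0
    radii:
    - 2.5
    - 9.0
    - 14.5
  background_class: background
- plaque_id: plaque11
  grid_shape:
  - 8
  - 36
  - 36
  voxel_size_um:
  - 120.0
  - 120.0
  - 120.0
  regions:
  - shape: ellipsoid
    label: fibrous
    center:
    - 4.5
    - 18.5
    - 18.5
    radii:
    - 3.5
    - 16.5
    - 16.5
  background_class: background
- plaque_id: plaque12
  grid_shape:
  - 8
  - 36
  - 36
  voxel_size_um:
  - 120.0
  - 120.0
  - 120.0
  regions:
  - shape: ellipsoid
    label: fibrous
    center:
    - 4.5
    - 18.5
    - 18.5
    radii:
    - 3.5
    - 16.5
    - 16.5
  background_class: background
protocols:
  vfa:
    tr: 10.0
    flip_angles:
    - 5.0
    - 10.0
    - 20.0
    - 30.0
    - 40.0
    te_fixed: 2.0
    noise_model: rician
    noise_sigma: 0.005
  multiecho:
    tr: 22.0
    echo_times:
    - 4.0
    - 8.0
    - 12.0
    - 16.0
    - 20.0
    flip_angle: 10.0
    noise_model: rician
    noise_sigma: 0.005
roi_plan:
  size_range:
  - 4
  - 9
  n_per_class:
    fibrous: 12
    lipid: 8
    inflammation: 6
    hemorrhage: 5
qda:
  scope: per_plaque
  shrinkage: 0.1
  priors: empirical
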