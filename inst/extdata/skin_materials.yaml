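# Default material configuration: four-layer skin stack plus tumor.
# thickness_mm — layer thickness; rho kg/m^3; cp J/(kg K); k W/(m K);
# mu_a, mu_s 1/mm at 1064 nm; g — scattering anisotropy factor.
layers:
  - name: epidermis
    thickness_mm: 0.08
    rho: 1200
    cp: 3589
    k: 0.235
    mu_a: 0.4
    mu_s: 45
    g: 0.8
  - name: papillary_dermis
    thickness_mm: 0.5
    rho: 1200
    cp: 3300
    k: 0.445
    mu_a: 0.38
    mu_s: 30
    g: 0.9
  - name: reticular_dermis
    thickness_mm: 0.6
    rho: 1200
    cp: 3300
    k: 0.445
    mu_a: 0.48
    mu_s: 25
    g: 0.8
  - name: subcutaneous_fat
    thickness_mm: 7.82
    rho: 1000
    cp: 2500
    k: 0.19
    mu_a: 0.43
    mu_s: 5
    g: 0.75
tumor:
  name: tumor
  diameter_mm: 10.0
  length_mm: 3.5
  top_depth_mm: 0.1
  rho: 1070
  cp: 3421
  k: 0.495
  mu_a: 0.08
  mu_s: 1.28
  g: 0.925
# Gold nanorod geometry and the mixed-tissue optical anchors (at the
# reference volume fraction) from which absorption/scattering efficiencies
# are calibrated at load time.
gnr:
  length_nm: 67
  diameter_nm: 10
  anchor_fv: 1.0e-3
  anchor_mu_a: 118.419
  anchor_mu_s: 6.101
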