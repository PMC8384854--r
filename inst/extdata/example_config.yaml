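# Example pipeline configuration. Omitted keys fall back to the package
# defaults (default_species_specs(), 2 specimens per spec, 20/40 landmarks,
# sections every 45 degrees, stage proxies 20 mm / 50 mm / maximal diameter).
generator:
  n_per_species: 2
  seed: 42
  n_points: 512
landmarks:
  k_suture: 20
  k_section: 40
  section_step: 45
  start_rule: ventral
sliding:
  max_iter: 10
  tol: 1.0e-8
stages:
  pre_hatching: 20
  middle: 50
  maturity: max
  pre_hatching_max_diameter: 30
stats:
  alpha: 0.05
output:
  dir: conchmorph_out
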