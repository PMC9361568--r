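# Demo configuration for the admixkit pipeline. Any omitted parameter falls
# back to default_config(); any stage input can be overridden with a file
# path under `inputs:` (see ?run_pipeline).
stages: [simulate, ancestry, ibd, ne, demography, recmap, ihs]
seed: 7
simulate:
  chrom_length_bp: 20000000
  background_rate: 2.0e-09     # 0.2 cM/Mb background
  hotspot_rate: 10            # hotspots per Mb
  hotspot_width_bp: 2000
  intensity_fold: 100
  shared_fraction: 0.8        # hotspot sharing of the sibling map
  n_per_pop: 11               # diploid founders per ancestry
  n_sites: 2000
  fst: 0.15
  base: KhoeSan
  events:
    - {ancestry: European, start_gen: 8, fraction: 0.01}
    - {ancestry: Bantu, start_gen: 14, fraction: 0.02}
  n_individuals: 50
  n_generations: 20
ancestry:
  switch_error_per_mb: 0.05
ibd:
  min_cm: 3                   # minimum segment length for Ne inference
  min_fraction: 0.9           # dual-coverage threshold for labelling
ne:
  grid_min: 4
  grid_max: 50
  smooth_penalty: 200
demography:
  bridge: geometric
recmap:
  bin_width: 2000
ihs:
  fraction: 0.01              # top |iHS| fraction for candidate extraction
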