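# Shipped default allocation & intensity configuration.
# Thresholds are data, not code: revise them against your own input layers.
cap_percentile: 0.90
rules:
  settlement:
    - var: population_density
      op: ">="
      threshold: 1000
  timber:
    - var: timber_cover
      op: ">="
      threshold: 0.5
  tree_crop:
    - var: tree_crop_cover
      op: ">="
      threshold: 0.5
  crop:
    - var: crop_cover
      op: ">="
      threshold: 0.5
  protected:
    # 1 where the pixel lies in a strictly protected area (IUCN I-III, plus
    # any per-country override list applied when building this layer)
    - var: protected_strict
      op: ">="
      threshold: 1
proxies:
  settlement:
    - var: population_density
      cap: true
  tree_crop:
    - var: population_density
      cap: true
  crop:
    - var: nitrogen_input
      cap: true
    - var: field_size
      cap: false
  untransformed:
    - var: livestock_density
      cap: true
      contextual: true
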