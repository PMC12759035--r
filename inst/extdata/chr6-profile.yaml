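# Default genotypic-similarity profile for chromosome 6 deletions.
# Dominating-effect gene concordance always gates; groups of >= 20 are
# accepted at HI-gene similarity >= 0.8, groups of >= 15 at 0.7 and 0.6;
# below that, only deletions containing a dominating-effect gene receive a
# description, at the highest threshold still yielding >= 15 members.
hi_threshold_grid: [1.0, 0.9, 0.8, 0.7, 0.6, 0.5, 0.4, 0.3, 0.2, 0.1, 0.0]
tier_rules:
  "1.0": 20
  "0.9": 20
  "0.8": 20
  "0.7": 15
  "0.6": 15
de_fallback_min_group: 15
prevalence_min: 0.20
min_carrier_count: 2
min_connections_for_ppv: 5
hi_similarity_mode: jaccard
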