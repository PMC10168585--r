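command: solve
config:
  model: /tmp/RtmpANFuMu/file43e6ffc60d1
  badflag: '1'
seed: 42
tool_version: 0.1.0
wall_time_s: 0.1563294
artifacts:
- ./solution.csv
- ./proteomaps.tsv
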