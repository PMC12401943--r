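# System geometry presets (mm; angles derived): the serialized form of
# make_geometry()'s built-ins.
common:
  source_to_iso: 541.0
  iso_to_detector: 408.0
  n_channels: 888
  channel_pitch_iso: 0.58
  row_pitch_iso: 0.625
geometries:
  VCT40:
    collimation: 40.0
    n_rows: 64
    spots: [0.0]
  VCT140:
    collimation: 140.0
    n_rows: 224
    spots: [0.0]
  DFSSD:
    collimation: 100.0
    n_rows: 160
    spots: [-45.0, 45.0]
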