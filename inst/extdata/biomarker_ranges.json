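{
  "apd90": [60, 330],
  "cv": [40, 110],
  "rmp": [-92, -65],
  "peak": [70, 140]
}
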