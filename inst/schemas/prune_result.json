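{
  "title": "prune result artifact",
  "required": ["cut_layer_id", "parameters_before", "parameters_after"]
}
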