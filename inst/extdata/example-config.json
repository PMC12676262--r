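{
  "subcommand": "compare",
  "seed": 11,
  "out_dir": "dynemu-out",
  "system": "lv",
  "n_inputs": 12,
  "n_time": 8,
  "ar_order": 1,
  "L": 50
}
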