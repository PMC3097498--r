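[
  {"name": "naoh", "low": 0.1, "high": 1.0, "units": "N"},
  {"name": "time", "low": 15, "high": 30, "units": "min"},
  {"name": "power", "low": 420, "high": 700, "units": "W"}
]
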