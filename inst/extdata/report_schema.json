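{
  "title": "locsig run report",
  "required": {
    "tool": "string",
    "version": "string",
    "seed": "integer",
    "parameters": "object",
    "regions": "list",
    "regions_core": "list",
    "minimal_signal": "list"
  },
  "interval_record": ["ref_id", "first", "last", "length"]
}
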