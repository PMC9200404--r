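{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "spnmeta pipeline metrics",
  "type": "object",
  "required": ["package_version", "seed", "stages"],
  "properties": {
    "package_version": {"type": "string"},
    "seed": {"type": "integer"},
    "stages": {
      "type": "object",
      "additionalProperties": {
        "type": "object",
        "additionalProperties": {
          "type": ["number", "string", "boolean", "integer"]
        }
      }
    }
  }
}
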