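{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "RorschachMap runConfig",
  "type": "object",
  "required": ["input", "stages", "mdsMetric", "somConfig", "autocmConfig", "seed", "topK"],
  "properties": {
    "input": {
      "description": "'fixture', a cohort CSV path, or a cohortSpec object",
      "type": "string"
    },
    "stages": {
      "type": "array",
      "minItems": 1,
      "items": {
        "enum": ["describe", "validate", "mds", "som", "autocm", "graph"]
      }
    },
    "mdsMetric": {
      "enum": ["manhattan", "euclidean"]
    },
    "somConfig": {
      "type": "object",
      "description": "list produced by somConfig()"
    },
    "autocmConfig": {
      "type": "object",
      "description": "list produced by autoCMConfig()"
    },
    "seed": {
      "type": "integer"
    },
    "outDir": {
      "type": ["string", "null"]
    },
    "topK": {
      "type": "integer",
      "minimum": 1
    }
  }
}
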