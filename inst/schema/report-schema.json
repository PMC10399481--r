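{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "dualphore screening report",
  "type": "object",
  "required": ["schema_version", "settings", "seed", "stage_counts",
               "survivors", "final_ranked"],
  "properties": {
    "schema_version": {"type": "string"},
    "settings": {
      "type": "object",
      "required": ["query", "library", "scores", "mode", "cutoff", "rules"],
      "properties": {
        "query": {"type": "string"},
        "library": {"type": "string"},
        "scores": {"type": "string"},
        "mode": {"enum": ["superpose", "in_place"]},
        "cutoff": {"type": "number", "exclusiveMinimum": 0},
        "rules": {
          "type": "array",
          "minItems": 1,
          "items": {
            "type": "object",
            "required": ["target", "cutoff", "strict"],
            "properties": {
              "target": {"type": "string"},
              "cutoff": {"type": "number"},
              "strict": {"type": "boolean"}
            }
          }
        }
      }
    },
    "seed": {"type": "integer"},
    "stage_counts": {
      "type": "object",
      "additionalProperties": {"type": "integer", "minimum": 0}
    },
    "survivors": {
      "type": "object",
      "additionalProperties": {
        "type": "array", "items": {"type": "string"}
      }
    },
    "match_rmsd": {
      "type": "object",
      "additionalProperties": {"type": "number", "minimum": 0}
    },
    "match_failures": {"type": "array", "items": {"type": "string"}},
    "final_ranked": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["compound_id", "score"],
        "properties": {
          "compound_id": {"type": "string"},
          "score": {"type": "number"}
        }
      }
    }
  }
}
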