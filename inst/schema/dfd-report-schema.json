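{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "dfdscan report",
  "type": "object",
  "required": ["n_leaves", "taxa", "losses", "events", "clusters", "summary"],
  "properties": {
    "n_leaves": {"type": "integer", "minimum": 0},
    "taxa": {"type": "array", "items": {"type": "string"}},
    "hybrids_excluded": {"type": "array", "items": {"type": "string"}},
    "losses": {"type": "integer", "minimum": 0},
    "events": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["gene_node", "species_label", "age_lower", "age_upper",
                     "child_species", "completeness", "verdict"],
        "properties": {
          "gene_node": {"type": "integer"},
          "species_label": {"type": "string"},
          "age_lower": {"type": "number", "minimum": 0},
          "age_upper": {"type": "number", "minimum": 0},
          "child_species": {
            "type": "array", "minItems": 2, "maxItems": 2,
            "items": {"type": "array", "items": {"type": "string"}}
          },
          "completeness": {
            "type": "array", "minItems": 2, "maxItems": 2,
            "items": {"type": "number", "minimum": 0, "maximum": 1}
          },
          "verdict": {
            "enum": ["DFD_LIKELY", "RETAINED_RECENT", "NON_DFD_LOSSY",
                     "AMBIGUOUS"]
          },
          "wgd_matches": {
            "type": "array",
            "items": {
              "type": "object",
              "required": ["name", "age_min", "age_max"],
              "properties": {
                "name": {"type": "string"},
                "age_min": {"type": "number"},
                "age_max": {"type": "number"}
              }
            }
          }
        }
      }
    },
    "clusters": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["name", "members", "species"],
        "properties": {
          "name": {"type": "string"},
          "members": {"type": "array", "items": {"type": "string"}},
          "species": {"type": "array", "items": {"type": "string"}},
          "coverage": {"type": "object"},
          "subclusters": {
            "type": "array",
            "items": {
              "type": "object",
              "required": ["name", "members"]
            }
          }
        }
      }
    },
    "summary": {"type": "array", "items": {"type": "string"}}
  }
}
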