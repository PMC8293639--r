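{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "HD centre capacity survey",
  "description": "Canonical JSON format for centre-level interview records: anticipated annual caseload for an intrathecally administered therapy, current FTE availability and willingness per resource class, and interview-reported component flags. Validation is performed by hdcapacity::validate_survey(); this document describes the format.",
  "type": "object",
  "required": ["centres"],
  "properties": {
    "metadata": {
      "type": "object",
      "description": "Free-text provenance: source, seed, generator parameters."
    },
    "centres": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["centre_id", "anticipated_patients_per_year", "resource_availability"],
        "properties": {
          "centre_id": {"type": "string"},
          "country": {"type": "string"},
          "anticipated_patients_per_year": {"type": "number", "minimum": 0},
          "resource_availability": {
            "type": "object",
            "description": "Available time per resource class, as an FTE fraction (>= 0).",
            "properties": {
              "proceduralist": {"type": "number", "minimum": 0},
              "nurse": {"type": "number", "minimum": 0},
              "facility": {"type": "number", "minimum": 0}
            }
          },
          "willingness": {
            "type": "object",
            "description": "Fraction of each staff class willing to perform/assist; missing classes default to 1.",
            "properties": {
              "proceduralist": {"type": "number", "minimum": 0, "maximum": 1},
              "nurse": {"type": "number", "minimum": 0, "maximum": 1},
              "facility": {"type": "number", "minimum": 0, "maximum": 1}
            }
          },
          "has_component": {
            "type": "object",
            "description": "Interview-reported presence of a dedicated component; defaults to availability > 0 when absent.",
            "properties": {
              "proceduralist": {"type": "boolean"},
              "nurse": {"type": "boolean"},
              "facility": {"type": "boolean"}
            }
          }
        }
      }
    }
  }
}
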