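{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "dbgvar starter neighborhood graph",
  "type": "object",
  "required": ["k", "starter", "sets", "nodes", "edges"],
  "properties": {
    "k": {"type": "integer", "minimum": 3, "maximum": 31},
    "starter": {"type": "integer", "minimum": 1},
    "sets": {"type": "array", "items": {"type": "string"}},
    "nodes": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id", "seq", "cov", "is_starter"],
        "properties": {
          "id": {"type": "integer", "minimum": 1},
          "seq": {"type": "string", "pattern": "^[ACGTN]+$"},
          "cov": {"type": "array", "items": {"type": "number", "minimum": 0}},
          "is_starter": {"type": "boolean"}
        }
      }
    },
    "edges": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["from", "to"],
        "properties": {
          "from": {"type": "integer", "minimum": 1},
          "to": {"type": "integer", "minimum": 1}
        }
      }
    }
  }
}
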