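{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "rxnsim native model format",
  "type": "object",
  "required": ["layers", "species", "reactions"],
  "properties": {
    "name": {"type": "string"},
    "layers": {"type": "array", "items": {"type": "string"}, "minItems": 1},
    "species": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id"],
        "properties": {
          "id": {"type": "string", "pattern": "^[A-Za-z_][A-Za-z0-9_]*$"},
          "display_name": {"type": "string"},
          "initial": {"type": "number", "minimum": 0},
          "type": {"enum": ["variable", "pool"]},
          "layer": {"type": "string"}
        }
      }
    },
    "shortcuts": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id", "target"],
        "properties": {
          "id": {"type": "string"},
          "target": {"type": "string"},
          "coef": {"type": "number", "exclusiveMinimum": 0},
          "layer": {"type": "string"}
        }
      }
    },
    "reactions": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id", "law"],
        "properties": {
          "id": {"type": "string"},
          "layer": {"type": "string"},
          "substrates": {"$ref": "#/$defs/participants"},
          "products": {"$ref": "#/$defs/participants"},
          "modifiers": {"$ref": "#/$defs/participants"},
          "law": {
            "type": "object",
            "required": ["kind"],
            "properties": {
              "kind": {"enum": ["mass_action", "michaelis_menten", "custom"]},
              "parameters": {"type": "object", "additionalProperties": {"type": "number"}},
              "expression": {"type": ["string", "null"]}
            }
          }
        }
      }
    },
    "rules": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id", "target", "expression"],
        "properties": {
          "id": {"type": "string"},
          "target": {"type": "string"},
          "expression": {"type": "string"},
          "layer": {"type": "string"}
        }
      }
    },
    "events": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id", "trigger", "assignments"],
        "properties": {
          "id": {"type": "string"},
          "trigger": {"type": "string"},
          "assignments": {"type": "object", "additionalProperties": {"type": "string"}},
          "layer": {"type": "string"}
        }
      }
    },
    "parameters": {"type": "object", "additionalProperties": {"type": "number"}}
  },
  "$defs": {
    "participants": {
      "type": "array",
      "items": {
        "type": "object",
        "oneOf": [
          {
            "required": ["species"],
            "properties": {
              "species": {"type": "string"},
              "coef": {"type": "number", "exclusiveMinimum": 0}
            }
          },
          {
            "required": ["shortcut"],
            "properties": {"shortcut": {"type": "string"}}
          }
        ]
      }
    }
  }
}
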