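{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "microflow network description",
  "description": "Pressure-driven microfluidic network for 1D lumped-element simulation. Every physical value is either a bare number in SI units or an object {value, unit}.",
  "type": "object",
  "additionalProperties": false,
  "$defs": {
    "quantity": {
      "oneOf": [
        {"type": "number"},
        {
          "type": "object",
          "required": ["value", "unit"],
          "additionalProperties": false,
          "properties": {
            "value": {"type": "number"},
            "unit": {"type": "string"}
          }
        }
      ]
    }
  },
  "properties": {
    "nodes": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id"],
        "additionalProperties": false,
        "properties": {
          "id": {"type": "string"},
          "is_ground": {"type": "boolean", "default": false},
          "is_sink": {"type": "boolean", "default": false}
        }
      }
    },
    "channels": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id", "node_a", "node_b", "width", "height", "length"],
        "additionalProperties": false,
        "properties": {
          "id": {"type": "string"},
          "node_a": {"type": "string"},
          "node_b": {"type": "string"},
          "width": {"$ref": "#/$defs/quantity"},
          "height": {"$ref": "#/$defs/quantity"},
          "length": {"$ref": "#/$defs/quantity"}
        }
      }
    },
    "pumps": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id", "node_from", "node_to", "kind", "value"],
        "additionalProperties": false,
        "properties": {
          "id": {"type": "string"},
          "node_from": {"type": "string"},
          "node_to": {"type": "string"},
          "kind": {"enum": ["flow_rate", "pressure"]},
          "value": {"$ref": "#/$defs/quantity"}
        }
      }
    },
    "fluids": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id", "viscosity"],
        "additionalProperties": false,
        "properties": {
          "id": {"type": "string"},
          "viscosity": {"$ref": "#/$defs/quantity"}
        }
      }
    },
    "species": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id", "diffusion_coefficient"],
        "additionalProperties": false,
        "properties": {
          "id": {"type": "string"},
          "diffusion_coefficient": {"$ref": "#/$defs/quantity"}
        }
      }
    },
    "injections": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["node", "concentrations"],
        "additionalProperties": false,
        "properties": {
          "node": {"type": "string"},
          "concentrations": {
            "type": "object",
            "additionalProperties": {"$ref": "#/$defs/quantity"}
          },
          "t_start": {"$ref": "#/$defs/quantity", "default": 0},
          "t_end": {"$ref": "#/$defs/quantity"}
        }
      }
    },
    "droplets": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id", "length", "channel"],
        "additionalProperties": false,
        "properties": {
          "id": {"type": "string"},
          "length": {"$ref": "#/$defs/quantity"},
          "b": {"type": "number", "default": 3},
          "channel": {"type": "string"},
          "t_inject": {"$ref": "#/$defs/quantity", "default": 0}
        }
      }
    },
    "membranes": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id", "channel", "area", "pore_radius", "porosity",
                     "thickness", "tank_volume"],
        "additionalProperties": false,
        "properties": {
          "id": {"type": "string"},
          "channel": {"type": "string"},
          "area": {"$ref": "#/$defs/quantity"},
          "pore_radius": {"$ref": "#/$defs/quantity"},
          "porosity": {"type": "number", "minimum": 0, "exclusiveMaximum": 1},
          "thickness": {"$ref": "#/$defs/quantity"},
          "tank_volume": {"$ref": "#/$defs/quantity"}
        }
      }
    },
    "settings": {
      "type": "object",
      "additionalProperties": false,
      "properties": {
        "max_time": {"$ref": "#/$defs/quantity"},
        "fixed_step": {"$ref": "#/$defs/quantity"},
        "max_events": {"type": "number"},
        "record": {"type": "boolean"}
      }
    }
  }
}
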