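{
  "format": "protpage-page-spec",
  "version": "1.0",
  "page": {
    "required": {"title": "string", "components": "array"},
    "optional": {"colors": "object"}
  },
  "kinds": {
    "markdown": {
      "required": {"text": "string"},
      "optional": {}
    },
    "table": {
      "required": {"columns": "array", "rows": "array"},
      "optional": {
        "page_size": "integer",
        "searchable": "boolean",
        "sortable": "boolean",
        "filterable": "boolean"
      }
    },
    "sequence": {
      "required": {"id": "string", "sequence": "string"},
      "optional": {"track": "array", "track_name": "string"}
    },
    "msa": {
      "required": {"ids": "array", "sequences": "array"},
      "optional": {}
    },
    "pair_alignment": {
      "required": {"side_a": "object", "side_b": "object"},
      "optional": {"matrix_name": "string", "show_structures": "boolean"}
    },
    "structure": {
      "required": {"sources": "array"},
      "optional": {"labels": "array"}
    },
    "network": {
      "required": {"nodes": "array", "edges": "array"},
      "optional": {}
    },
    "plot": {
      "required": {"traces": "array"},
      "optional": {"layout": "object"}
    }
  }
}
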