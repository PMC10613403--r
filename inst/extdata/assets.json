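{
  "comment": "pinned third-party browser assets; versions fixed for reproducible builds",
  "ngl": "https://cdn.jsdelivr.net/npm/ngl@2.0.0-dev.40/dist/ngl.js",
  "cytoscape": "https://cdn.jsdelivr.net/npm/cytoscape@3.28.1/dist/cytoscape.min.js",
  "plotly": "https://cdn.plot.ly/plotly-2.27.0.min.js"
}
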