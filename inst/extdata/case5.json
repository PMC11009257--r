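{
  "name": "case5_printed_resistances",
  "nodes": [
    {
      "id": "l_ica_in",
      "kind": "inlet"
    },
    {
      "id": "r_ica_in",
      "kind": "inlet"
    },
    {
      "id": "ba_in",
      "kind": "inlet"
    },
    {
      "id": "l_jt",
      "kind": "junction"
    },
    {
      "id": "r_jt",
      "kind": "junction"
    },
    {
      "id": "ba_top",
      "kind": "junction"
    },
    {
      "id": "an",
      "kind": "aneurysm"
    },
    {
      "id": "l_mca_out",
      "kind": "outlet"
    },
    {
      "id": "r_mca_out",
      "kind": "outlet"
    },
    {
      "id": "l_a2_out",
      "kind": "outlet"
    },
    {
      "id": "r_a2_out",
      "kind": "outlet"
    },
    {
      "id": "l_pca_out",
      "kind": "outlet"
    },
    {
      "id": "r_pca_out",
      "kind": "outlet"
    }
  ],
  "segments": [
    {
      "id": "l_ica",
      "label": "left_ICA",
      "from": "l_ica_in",
      "to": "l_jt",
      "length": 0.02,
      "radius": 0.002,
      "resistance_override": 0.0261446428571429
    },
    {
      "id": "r_ica",
      "label": "right_ICA",
      "from": "r_ica_in",
      "to": "r_jt",
      "length": 0.02,
      "radius": 0.002,
      "resistance_override": 0.0261446428571429
    },
    {
      "id": "ba",
      "label": "BA",
      "from": "ba_in",
      "to": "ba_top",
      "length": 0.025,
      "radius": 0.0015,
      "resistance_override": 0.103287477954145
    },
    {
      "id": "l_a1",
      "label": "left_A1",
      "from": "l_jt",
      "to": "an",
      "length": 0.014,
      "radius": 0.0011,
      "resistance_override": 0.089
    },
    {
      "id": "r_a1",
      "label": "right_A1",
      "from": "r_jt",
      "to": "an",
      "length": 0.014,
      "radius": 0.0011,
      "resistance_override": 0.472
    },
    {
      "id": "l_a2",
      "label": "left_A2",
      "from": "an",
      "to": "l_a2_out",
      "length": 0.022,
      "radius": 0.0011,
      "resistance_override": 0.285
    },
    {
      "id": "r_a2",
      "label": "right_A2",
      "from": "an",
      "to": "r_a2_out",
      "length": 0.022,
      "radius": 0.0011,
      "resistance_override": 0.211
    },
    {
      "id": "l_mca",
      "label": "left_MCA",
      "from": "l_jt",
      "to": "l_mca_out",
      "length": 0.03,
      "radius": 0.0014,
      "resistance_override": 0.16333596120664
    },
    {
      "id": "r_mca",
      "label": "right_MCA",
      "from": "r_jt",
      "to": "r_mca_out",
      "length": 0.03,
      "radius": 0.0014,
      "resistance_override": 0.16333596120664
    },
    {
      "id": "l_pcom",
      "label": "left_PCom",
      "from": "l_jt",
      "to": "ba_top",
      "length": 0.015,
      "radius": 0.0007,
      "resistance_override": 1.30668768965312
    },
    {
      "id": "r_pcom",
      "label": "right_PCom",
      "from": "r_jt",
      "to": "ba_top",
      "length": 0.015,
      "radius": 0.0007,
      "resistance_override": 1.30668768965312
    },
    {
      "id": "l_pca",
      "label": "left_PCA",
      "from": "ba_top",
      "to": "l_pca_out",
      "length": 0.03,
      "radius": 0.001,
      "resistance_override": 0.627471428571429
    },
    {
      "id": "r_pca",
      "label": "right_PCA",
      "from": "ba_top",
      "to": "r_pca_out",
      "length": 0.03,
      "radius": 0.001,
      "resistance_override": 0.627471428571429
    }
  ],
  "roles": {
    "left_A1": "l_a1",
    "right_A1": "r_a1",
    "left_A2": "l_a2",
    "right_A2": "r_a2",
    "posterior": ["ba", "l_pcom", "r_pcom", "l_pca", "r_pca"]
  },
  "variant": "complete",
  "inlets": {
    "l_ica_in": "left_ICA",
    "r_ica_in": "right_ICA",
    "ba_in": "BA"
  }
}
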