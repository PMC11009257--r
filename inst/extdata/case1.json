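{
  "name": "synthetic_hypoplastic_a1_seed101",
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
      "radius": 0.00205601629538187
    },
    {
      "id": "r_ica",
      "label": "right_ICA",
      "from": "r_ica_in",
      "to": "r_jt",
      "length": 0.02,
      "radius": 0.00193363178469106
    },
    {
      "id": "ba",
      "label": "BA",
      "from": "ba_in",
      "to": "ba_top",
      "length": 0.025,
      "radius": 0.00148334865975654
    },
    {
      "id": "l_a1",
      "label": "left_A1",
      "from": "l_jt",
      "to": "an",
      "length": 0.014,
      "radius": 0.0011
    },
    {
      "id": "r_a1",
      "label": "right_A1",
      "from": "r_jt",
      "to": "an",
      "length": 0.014,
      "radius": 0.000566326809740909
    },
    {
      "id": "l_a2",
      "label": "left_A2",
      "from": "an",
      "to": "l_a2_out",
      "length": 0.022,
      "radius": 0.0011
    },
    {
      "id": "r_a2",
      "label": "right_A2",
      "from": "an",
      "to": "r_a2_out",
      "length": 0.022,
      "radius": 0.000899643394945673
    },
    {
      "id": "l_mca",
      "label": "left_MCA",
      "from": "l_jt",
      "to": "l_mca_out",
      "length": 0.03,
      "radius": 0.00141508586265161
    },
    {
      "id": "r_mca",
      "label": "right_MCA",
      "from": "r_jt",
      "to": "r_mca_out",
      "length": 0.03,
      "radius": 0.00142192373464773
    },
    {
      "id": "l_pcom",
      "label": "left_PCom",
      "from": "l_jt",
      "to": "ba_top",
      "length": 0.015,
      "radius": 0.000742318687858969
    },
    {
      "id": "r_pcom",
      "label": "right_PCom",
      "from": "r_jt",
      "to": "ba_top",
      "length": 0.015,
      "radius": 0.000721996165418998
    },
    {
      "id": "l_pca",
      "label": "left_PCA",
      "from": "ba_top",
      "to": "l_pca_out",
      "length": 0.03,
      "radius": 0.000994379140737639
    },
    {
      "id": "r_pca",
      "label": "right_PCA",
      "from": "ba_top",
      "to": "r_pca_out",
      "length": 0.03,
      "radius": 0.00104691884241444
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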