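{
  "regions": [
    {
      "id": "chest",
      "display_name": "chest",
      "patterns": [
        "chest"
      ]
    },
    {
      "id": "lungs",
      "display_name": "lungs",
      "patterns": [
        "lungs",
        "pulmonary"
      ]
    },
    {
      "id": "left_lung",
      "display_name": "left lung",
      "patterns": [
        "left lung"
      ]
    },
    {
      "id": "right_lung",
      "display_name": "right lung",
      "patterns": [
        "right lung"
      ]
    },
    {
      "id": "abdomen",
      "display_name": "abdomen",
      "patterns": [
        "abdomen"
      ]
    },
    {
      "id": "liver",
      "display_name": "liver",
      "patterns": [
        "liver",
        "hepatic"
      ]
    },
    {
      "id": "spleen",
      "display_name": "spleen",
      "patterns": [
        "spleen",
        "splenic"
      ]
    },
    {
      "id": "inguinal_lymph_nodes",
      "display_name": "inguinal lymph nodes",
      "patterns": [
        "inguinal lymph nodes",
        "inguinal lymphadenopathy"
      ]
    }
  ],
  "edges": [
    {
      "parent": "chest",
      "child": "lungs"
    },
    {
      "parent": "lungs",
      "child": "left_lung"
    },
    {
      "parent": "lungs",
      "child": "right_lung"
    },
    {
      "parent": "abdomen",
      "child": "liver"
    },
    {
      "parent": "abdomen",
      "child": "spleen"
    }
  ]
}
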