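{
  "comment": "Editable gating rules and scored positions for PETase typing. Positions refer to the packaged synthetic IIb-like reference annotation.",
  "templates": [
    {
      "type_label": "I",
      "n_disulfides": 1,
      "extended_loop": false,
      "scored_positions": [
        {"ref_pos": 94, "expected": "A", "weight": 1},
        {"ref_pos": 95, "expected": "L", "weight": 1},
        {"ref_pos": 100, "expected": "V", "weight": 1}
      ]
    },
    {
      "type_label": "IIa",
      "n_canonical": 2,
      "extended_loop": true,
      "scored_positions": [
        {"ref_pos": 94, "expected": "G", "weight": 1},
        {"ref_pos": 95, "expected": "A", "weight": 1},
        {"ref_pos": 100, "expected": "G", "weight": 1},
        {"ref_pos": 246, "expected": "A", "weight": 1},
        {"ref_pos": 247, "expected": "S", "weight": 1},
        {"ref_pos": 248, "expected": "D", "weight": 1}
      ]
    },
    {
      "type_label": "IIb",
      "n_canonical": 2,
      "extended_loop": true,
      "scored_positions": [
        {"ref_pos": 94, "expected": "N", "weight": 1},
        {"ref_pos": 95, "expected": "Q", "weight": 1},
        {"ref_pos": 100, "expected": "T", "weight": 1},
        {"ref_pos": 246, "expected": "V", "weight": 1},
        {"ref_pos": 247, "expected": "G", "weight": 1},
        {"ref_pos": 248, "expected": "N", "weight": 1}
      ]
    },
    {
      "type_label": "III",
      "min_disulfides": 2,
      "all_noncanonical": true,
      "motifs": ["GHSQG"],
      "clamp": false,
      "loop3_delta_min": 3,
      "scored_positions": [
        {"ref_pos": 93, "expected": "T", "weight": 1},
        {"ref_pos": 94, "expected": "S", "weight": 1},
        {"ref_pos": 95, "expected": "G", "weight": 1}
      ]
    }
  ]
}
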