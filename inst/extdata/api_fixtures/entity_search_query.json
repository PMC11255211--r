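{
  "entities": [
    {
      "pdb_id": "1TST",
      "entity_id": 1,
      "chain_ids": ["A", "C"],
      "author_chain_map": {},
      "method": "X-Ray Diffraction",
      "resolution": 1.48,
      "r_free": 0.19,
      "num_chains": 2
    },
    {
      "pdb_id": "1TST",
      "entity_id": 2,
      "chain_ids": ["B"],
      "author_chain_map": {"X": "B"},
      "method": "X-Ray Diffraction",
      "resolution": 1.48,
      "r_free": 0.19,
      "num_chains": 2
    },
    {
      "pdb_id": "2LOW",
      "entity_id": 1,
      "chain_ids": ["A"],
      "author_chain_map": {},
      "method": "X-Ray Diffraction",
      "resolution": 4.2,
      "r_free": 0.28,
      "num_chains": 1
    },
    {
      "pdb_id": "3NMR",
      "entity_id": 1,
      "chain_ids": ["A"],
      "author_chain_map": {},
      "method": "Solution NMR",
      "resolution": 1.0,
      "r_free": 0.1,
      "num_chains": 1
    },
    {
      "pdb_id": "4BIG",
      "entity_id": 1,
      "chain_ids": ["A"],
      "author_chain_map": {},
      "method": "X-Ray Diffraction",
      "resolution": 2.0,
      "r_free": 0.22,
      "num_chains": 24
    }
  ]
}
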