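{
  "title": "Test protein in complex with fructose 6-phosphate",
  "description": "Synthetic recorded response for a test entry",
  "deposition_date": "2005-03-14",
  "resolution": 1.48,
  "resolution_low": 48.2,
  "r_free": 0.19,
  "r_work": 0.17,
  "space_group": "P 21 21 21",
  "chains": {
    "A": {
      "uniprot_ids": ["P12345"],
      "ena_id": "AB123456",
      "entity_description": "Test protein",
      "entity_source_org": "Gallus gallus",
      "entity_source_org_id": "9031",
      "entity_host_org": "Escherichia coli",
      "entity_host_org_id": "562",
      "cg_ph": "7.0",
      "cg_temp": "295",
      "chain_ligands": ["K6P"],
      "ligands": ["K6P", "EOH"],
      "entity_chains": ["A", "C"],
      "entity_auth_chains": ["A", "C"],
      "chain_entities": "1",
      "chain_to_auth_chain": "A",
      "entity_sequence": "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ"
    },
    "B": {
      "uniprot_ids": ["P11111", "P22222"],
      "entity_description": "Chimeric construct",
      "entity_chains": ["B"],
      "entity_auth_chains": ["X"],
      "chain_entities": "2",
      "chain_to_auth_chain": "X",
      "entity_sequence": "GSHMLVPRGS"
    },
    "C": {
      "uniprot_ids": ["P12345"],
      "ena_id": "AB123456",
      "entity_description": "Test protein",
      "entity_chains": ["A", "C"],
      "entity_auth_chains": ["A", "C"],
      "chain_entities": "1",
      "chain_to_auth_chain": "C",
      "entity_sequence": "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ"
    }
  }
}
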