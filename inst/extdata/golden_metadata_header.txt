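pdb_id,unp_id,ena_id,seq_len,num_altlocs,title,description,entity_description,deposition_date,entity_source_org,entity_source_org_id,entity_host_org,entity_host_org_id,resolution,resolution_low,r_free,r_work,space_group,cg_ph,cg_temp,chain_ligands,ligands,entity_chains,entity_auth_chains,chain_entities,chain_to_auth_chain,entity_sequence,num_altloc_segments,cluster_id
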