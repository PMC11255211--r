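pdb_id,unp_id,pdb_idx,unp_idx,seg_id,res_name,res_icode,res_hflag,rel_loc,codon,codon_score,codon_opts,secondary,phi,phi_A,phi_B,phi_C,phi_D,psi,psi_A,psi_B,psi_C,psi_D,omega,omega_A,omega_B,omega_C,omega_D,bfactor,bfactor_A,bfactor_B,bfactor_C,bfactor_D,contact_count,contact_count_A,contact_count_B,contact_count_C,contact_count_D,contact_types,contact_types_A,contact_types_B,contact_types_C,contact_types_D,contact_smax,contact_smax_A,contact_smax_B,contact_smax_C,contact_smax_D,contact_ooc,contact_ooc_A,contact_ooc_B,contact_ooc_C,contact_ooc_D,contact_non_aa,contact_non_aa_A,contact_non_aa_B,contact_non_aa_C,contact_non_aa_D,contact_aas,contact_aas_A,contact_aas_B,contact_aas_C,contact_aas_D,num_altlocs,altlocs_N,altlocs_CA,altlocs_C,dist_CA_AB,dist_CA_AC,dist_CA_AD,dist_CA_BC,dist_CA_BD,dist_CA_CD,dist_CA_AB_norm,dist_CA_AC_norm,dist_CA_AD_norm,dist_CA_BC_norm,dist_CA_BD_norm,dist_CA_CD_norm,sigma_CA_A,sigma_CA_B,sigma_CA_C,sigma_CA_D,n_terminal_dist,c_terminal_dist
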