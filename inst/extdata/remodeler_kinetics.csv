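factor,catalytic_subunit,F_bound,F_bound_se,f_sb,f_sb_se,tau_sb,tau_sb_se,tau_tb,tau_tb_source,tau_search,tau_search_se,SI,SI_se,occupancy_pct,occupancy_pct_se,N_targets,N_molecules
RSC,Sth1,0.660,0.011,0.27,0.02,5.0,0.7,0.5,assumed,15,2.6,17,3.3,30,7.3,3702,4355
SWI/SNF,Snf2,0.559,0.013,0.24,0.06,4.4,1.2,0.5,assumed,NA,NA,4.7,1.6,94,41,466,NA
INO80,Ino80,0.483,0.002,0.20,0.03,3.7,0.8,0.5,assumed,23,6.0,15,4.7,25,9.7,1646,NA
ISW2,Isw2,0.348,0.010,0.13,0.03,4.9,2.2,0.5,assumed,61,30,44,21,11,7.2,1802,NA
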