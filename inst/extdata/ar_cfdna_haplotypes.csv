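sample,patient,haplotype,mutant_reads,wildtype_reads,total_reads,percent_mutant,wga2
VC-001-t1,VC-001,T878A,39,13231,13270,0.29,TRUE
VC-001-t1,VC-001,H875Y,36,13351,13387,0.27,TRUE
VC-001-t1,VC-001,H875Y/T878A,251,13019,13270,1.89,TRUE
VC-001-t2,VC-001,T878A,30,12626,12656,0.24,FALSE
VC-001-t2,VC-001,H875Y,0,13307,13307,0.00,FALSE
VC-001-t2,VC-001,H875Y/T878A,230,12426,12656,1.82,FALSE
VC-001-t2,VC-001,T878A/D891H,158,10383,10541,1.50,FALSE
VC-001-t2,VC-001,D891H,8,10533,10541,0.08,FALSE
VC-005,VC-005,E894K,170,10745,10915,1.56,FALSE
VC-012-t1,VC-012,M896V,1270,5985,7255,17.51,FALSE
VC-012-t1,VC-012,S889G,307,4769,5076,6.05,TRUE
VC-012-t1,VC-012,M896V,273,5838,6111,4.47,TRUE
VC-012-t2,VC-012,S889G,103,8202,8305,1.24,FALSE
VC-012-t2,VC-012,M896V,31,8934,8965,0.35,FALSE
VC-012-t2,VC-012,H875Y,49,10355,10404,0.47,FALSE
VC-012-t2,VC-012,T878A,300,9760,10060,2.98,FALSE
VC-012-t2,VC-012,F877L/T878A,141,9919,10060,1.40,FALSE
VC-012-t2,VC-012,T878A/S889G,35,8270,8305,0.42,FALSE
VC-014,VC-014,E898G,237,11919,12156,1.95,TRUE
VC-015,VC-015,T878A,218,9502,9720,2.24,FALSE
VC-017,VC-017,T878A,99,12626,12725,0.78,FALSE
VC-018,VC-018,H875Y,223,10382,10605,2.10,TRUE
VC-021,VC-021,H875Q,251,9846,10097,2.49,TRUE
VC-021,VC-021,T919S,238,9004,9242,2.58,TRUE
VC-022,VC-022,D880E,12,10902,10914,0.11,FALSE
VC-040,VC-040,H875Y,479,7560,8039,5.96,FALSE
VC-041-t1,VC-041,H875Y,1521,7260,8781,17.32,FALSE
VC-041-t2,VC-041,H875Y,4665,15662,20327,22.95,FALSE
VC-053,VC-053,H875Y,136,9064,9200,1.48,FALSE
VC-063,VC-063,H875Y,270,14874,15144,1.78,FALSE
VC-064,VC-064,L882I,17,15670,15687,0.11,FALSE
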