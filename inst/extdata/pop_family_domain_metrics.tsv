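pdb_id	protein	reported_conformation	residues	d_ca_ser_his	d_og_ne2	d_ca_his_asp	d_od_nd1	com_distance	buried_catalytic	buried_propeller	interface_res_catalytic	interface_res_propeller	hbonds	salt_bridges
7OB1	PSP	intermediate	677	18.2	13.9	10.6	9.0	32.3	11.3	9.4	16.3	15.9	11	4
4BP8	TbOpB	open	712	18.5	18.3	7.6	11.8	36.7	8.4	7.5	10.3	10.5	14	4
4BP9	TbOpB	closed	710	8.3	3.5	4.5	3.1	30.4	14.0	12.3	17.4	16.9	28	4
3IUL	ApPEP	open	669	NA	NA	NA	NA	38.7	8.1	7.7	12.1	7.7	7	NA
3IVM	ApPEP	closed	682	8.3	3.3	4.5	2.9	30.7	16.9	14.6	22.4	19.5	22	2
5N4F	GmPEP	open	703	NA	NA	NA	NA	39.4	7.5	7.0	11.0	6.3	9	NA
5N4C	GmPEP	intermediate	720	15.6	NA	8.4	10.6	32.0	13.5	11.4	19.0	15.2	25	1
5T88	PfPEP	intermediate	618	23.6	17.4	10.9	7.0	30.9	12.2	11.5	18.5	15.1	16	1
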