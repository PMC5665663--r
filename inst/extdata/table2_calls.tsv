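sample	type	first_label	last_label	mean_ratio	mean_z
GL133	het_del	promoter	exon1	0.62	-6.1
GL474	het_del	promoter	exon1	0.43	-9.8
GL2180	het_del	promoter	exon1	0.58	-5.6
GL3185	het_del	promoter	exon1	0.51	-6.2
GL3767	het_del	promoter	exon1	0.50	-8.2
GL4120	het_del	promoter	exon1	0.53	-7.9
GL4631	het_del	promoter	exon1	0.52	-8.7
GL6406	het_del	promoter	exon1	0.56	-8.7
GL8496	het_del	promoter	exon1	0.51	-8.6
GL8874	het_del	promoter	exon1	0.52	-7.9
GL9037	het_del	promoter	exon1	0.51	-7.5
GL12366	het_del	promoter	exon1	0.59	-6.6
GL12367	het_del	promoter	exon1	0.55	-5.4
GL12533	het_del	promoter	exon1	0.51	-6.2
GL14152	het_del	promoter	exon1	0.59	-6.0
GL14549	het_del	promoter	exon1	0.51	-8.0
GL15102	het_del	promoter	exon1	0.59	-6.6
GL15358	het_del	promoter	exon1	0.46	-8.7
GL15491	het_del	promoter	exon1	0.51	-8.1
GL15561	het_del	promoter	exon1	0.57	-6.2
GL15575	het_del	promoter	exon1	0.51	-9.8
GL15992	het_del	promoter	exon1	0.57	-6.8
GL14257	het_del	promoter	exon2	0.57	-5.6
GL14258	het_del	promoter	exon2	0.50	-9.5
GL5014	het_del	promoter	exon6	0.54	-7.4
GL8531	het_del	exon2	exon3	0.56	-6.7
GL15929	het_del	exon2	exon6	0.54	-9.7
GL9910	dup	exon2	exon6	1.38	11.8
GL6260	het_del	exon3	exon6	0.53	-9.7
GL15692	het_del	exon5	exon6	0.54	-14.7
GL12812	dup	exon7	exon7	1.47	7.3
GL5843	dup	exon11	exon12	1.86	12.7
GL12450	het_del	exon11	exon12	0.54	-7.8
GL15560	het_del	exon13	exon14	0.52	-15.9
GL15110	het_del	exon13	exon15	0.65	-8.7
GL5799	het_del	exon16	exon18	0.53	-9.9
GL4789	het_del	exon17	exon18	0.53	-9.3
GL2381	het_del	exon17	exon18	0.55	-10.1
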