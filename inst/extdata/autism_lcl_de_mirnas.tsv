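clone_id	mirna_name	log2_ratio	p_value
SM10801	hsa-miR-182-AS	-1.54	1.44E-03
hSQ018350	hsa-miR-136	-1.50	2.28E-03
SM10637	hsa-miR-518a	-1.45	3.52E-03
hSQ045460	hsa-miR-153-1	-1.41	5.07E-03
SM11115	hsa-miR-520b	-1.38	6.71E-03
SM10529	hsa-miR-455	-1.30	1.25E-02
hHM044864	hsa-miR-326	-1.24	1.95E-02
SM10553	hsa-miR-199b	-1.23	1.96E-02
miR211	hsa-miR-211	-1.23	2.04E-02
hSQ016068	hsa-miR-132	-1.22	2.20E-02
SM10792	hsa-miR-495	-1.20	2.43E-02
hSQ025962	hsa-miR-16-2	-1.19	2.54E-02
hHM044822	hsa-miR-190	-1.18	2.69E-02
hHM044960	hsa-miR-219	-1.17	2.98E-02
hHM045056	hsa-miR-148b	-1.16	3.01E-02
hHM044897	hsa-miR-189	-1.16	3.06E-02
hHM045063	hsa-miR-133b	-1.13	3.59E-02
hSQ018899	hsa-miR-106b	-1.11	4.11E-02
hHM044849	hsa-miR-367	-1.10	4.21E-02
SM10740	hsa-miR-139	-1.10	4.32E-02
hHM044819	hsa-miR-185	1.44	4.04E-03
hHM044919	hsa-miR-103	1.31	1.20E-02
hHM044733	hsa-miR-107	1.26	1.68E-02
hHM044918	hsa-miR-29b	1.24	1.88E-02
hHM045013	hsa-miR-194	1.22	2.11E-02
SM10729	hsa-miR-524	1.22	2.21E-02
hHM044804	hsa-miR-191	1.21	2.23E-02
SM11334	hsa-miR-376a-AS	1.19	2.53E-02
SM10789	hsa-miR-451	1.19	2.64E-02
hHM044971	hsa-miR-23b	1.17	2.95E-02
miR195	hsa-miR-195	1.16	3.02E-02
SM10711	hsa-miR-23b	1.16	3.03E-02
SM10310	hsa-miR-342	1.15	3.24E-02
SM10644	hsa-miR-23a	1.14	3.36E-02
hSQ001775	hsa-miR-186	1.14	3.43E-02
miR25	hsa-miR-25	1.14	3.55E-02
SM10575	hsa-miR-519c	1.13	3.71E-02
SM10238	hsa-miR-346	1.12	3.80E-02
hHM044950	hsa-miR-205	1.12	3.80E-02
hHM044743	hsa-miR-30c	1.11	3.98E-02
hSQ027766	hsa-miR-93	1.10	4.18E-02
hHM045009	hsa-miR-186	1.08	4.67E-02
hHM044831	hsa-miR-106b	1.08	4.86E-02
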