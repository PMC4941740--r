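sample_id	raw_reads	raw_bases_mb	raw_mean_len	filt_reads	filt_bases_mb	filt_mean_len	pct_passed	pct_on_target
BLP1	468655	179.2	382	434193	149.6	344	92.6	70.6
BLP2	544069	206.1	379	503649	173	343	92.6	71.7
BHP1	604742	229.7	380	555099	195	351	91.8	63.3
BHP2	629606	240.7	382	580983	204.8	352	92.3	65.5
MLP2	573466	213	371	530089	176.3	332	92.4	67.2
MLP5	437957	165.4	378	407996	137.1	336	93.2	73.3
MHP1	544403	197.3	362	498613	163.2	327	91.6	70.2
MHP2	657400	238.4	363	602554	197.3	327	91.7	62.8
JLP1	632961	249	393	594251	213.9	359	93.9	65.3
JLP2	576284	227.3	394	541456	195.4	360	94	66.3
JHP1	447055	172.3	385	413569	145.1	350	92.5	76.4
JHP2	445066	180	404	413702	151.7	366	93	74.3
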