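sample	hap	chrom	start_cM	end_cM	ancestry
ex0001	1	chr1	0	60	3
ex0001	1	chr2	0	40	3
ex0001	1	chrX	0	30	3
ex0001	2	chr1	0	55.534673393704	3
ex0001	2	chr1	55.534673393704	60	2
ex0001	2	chr2	0	40	3
ex0002	1	chr1	0	60	3
ex0002	1	chr2	0	40	3
ex0002	1	chrX	0	30	3
ex0002	2	chr1	0	60	3
ex0002	2	chr2	0	40	1
ex0003	1	chr1	0	9.84833597671241	1
ex0003	1	chr1	9.84833597671241	60	2
ex0003	1	chr2	0	40	1
ex0003	1	chrX	0	30	1
ex0003	2	chr1	0	4.00382766500115	2
ex0003	2	chr1	4.00382766500115	32.4973183125257	3
ex0003	2	chr1	32.4973183125257	60	2
ex0003	2	chr2	0	40	2
ex0003	2	chrX	0	30	2
ex0004	1	chr1	0	60	3
ex0004	1	chr2	0	40	1
ex0004	1	chrX	0	30	3
ex0004	2	chr1	0	55.534673393704	3
ex0004	2	chr1	55.534673393704	60	2
ex0004	2	chr2	0	40	3
ex0004	2	chrX	0	30	3
ex0005	1	chr1	0	47.2151959128678	3
ex0005	1	chr1	47.2151959128678	60	2
ex0005	1	chr2	0	28.0661673936993	3
ex0005	1	chr2	28.0661673936993	40	2
ex0005	1	chrX	0	30	3
ex0005	2	chr1	0	55.534673393704	3
ex0005	2	chr1	55.534673393704	60	2
ex0005	2	chr2	0	40	3
ex0006	1	chr1	0	60	3
ex0006	1	chr2	0	1.04397912509739	3
ex0006	1	chr2	1.04397912509739	15.1787405274808	2
ex0006	1	chr2	15.1787405274808	40	3
ex0006	1	chrX	0	30	3
ex0006	2	chr1	0	14.4456984009594	2
ex0006	2	chr1	14.4456984009594	60	3
ex0006	2	chr2	0	34.7672015242279	2
ex0006	2	chr2	34.7672015242279	40	3
ex0006	2	chrX	0	30	2
ex0007	1	chr1	0	60	3
ex0007	1	chr2	0	16.440089372918	3
ex0007	1	chr2	16.440089372918	40	1
ex0007	1	chrX	0	30	3
ex0007	2	chr1	0	45.6369848968461	1
ex0007	2	chr1	45.6369848968461	60	3
ex0007	2	chr2	0	40	3
ex0007	2	chrX	0	30	3
ex0008	1	chr1	0	60	3
ex0008	1	chr2	0	40	3
ex0008	1	chrX	0	30	3
ex0008	2	chr1	0	50.9766646055505	1
ex0008	2	chr1	50.9766646055505	60	3
ex0008	2	chr2	0	40	3
ex0008	2	chrX	0	30	3
ex0009	1	chr1	0	60	3
ex0009	1	chr2	0	40	3
ex0009	1	chrX	0	30	3
ex0009	2	chr1	0	55.534673393704	3
ex0009	2	chr1	55.534673393704	60	2
ex0009	2	chr2	0	40	3
ex0010	1	chr1	0	60	3
ex0010	1	chr2	0	40	3
ex0010	1	chrX	0	30	3
ex0010	2	chr1	0	60	1
ex0010	2	chr2	0	40	1
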