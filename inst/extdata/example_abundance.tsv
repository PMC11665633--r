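feature_id	sample001	sample002	sample003	sample004	sample005	sample006	sample007	sample008	sample009	sample010	sample011	sample012	sample013	sample014	sample015	sample016	sample017	sample018	sample019	sample020	sample021	sample022	sample023	sample024	sample025	sample026	sample027	sample028	sample029	sample030
k__Bacteria|p__Firmicutes|c__Clostridia|g__Gen01	56160	5455	15587	19482	161126	30472	3964	52069	19114	30256	122459	21616	30595	34528	16238	98326	670253	104123	54551	172361	275207	392205	279465	403343	10252	329510	374641	44085	70699	212846
k__Bacteria|p__Bacteroidota|g__Gen02	239240	90015	89819	437676	195620	40141	84219	225109	218348	86804	183743	44726	56813	57892	385796	17963	21978	118740	45302	33277	6723	4610	22470	9755	54232	20386	6693	20681	65493	35835
k__Bacteria|p__Proteobacteria|g__Gen03	29003	34180	21833	35603	77156	6705	207937	13054	13458	25434	93106	2891	16791	54469	77352	108250	73982	53680	48261	131586	190187	245474	141900	112742	167434	66171	62693	157366	105231	364268
k__Bacteria|p__Actinobacteria|g__Gen04	105880	18228	60486	52553	124979	93444	267188	186821	145844	102810	102500	45876	272072	32156	71327	198158	6127	54012	2707	17997	19946	26134	17119	47175	23932	20148	16446	33690	10734	33577
k__Bacteria|p__Firmicutes|c__Clostridia|g__Gen05	87265	22124	17898	0	6507	48104	7478	10848	69087	42613	37163	17995	0	27282	4141	10471	0	124814	58377	75056	190540	22025	17689	0	27124	25278	39236	5795	17651	15380
k__Bacteria|p__Bacteroidota|g__Gen06	73835	5232	6238	6641	24807	9699	623	28396	6695	0	4339	35241	0	38205	14163	21405	1665	0	63551	39024	7978	4970	24924	4123	8464	0	59821	15275	9385	4674
k__Bacteria|p__Proteobacteria|g__Gen07	36774	20422	68061	0	0	37457	17597	23402	9209	51826	25802	29502	13810	24089	51901	14964	0	101025	49686	16747	2893	3891	4587	34152	22373	8543	13466	0	33186	40150
k__Bacteria|p__Actinobacteria|g__Gen08	19987	12503	0	51277	60594	0	9823	25987	23767	15513	19954	66539	33148	125769	59588	26227	11042	0	47608	16060	100239	0	84744	2444	2254	0	13818	26254	0	3807
k__Bacteria|p__Firmicutes|c__Clostridia|g__Gen09	5082	63836	60689	3452	8299	23023	4985	6318	37831	12297	31044	19655	14788	18889	65062	15828	15637	7650	6278	44030	14599	18716	12610	4871	15542	13435	14511	276843	39671	12361
k__Bacteria|p__Bacteroidota|g__Gen10	11485	13726	44018	27360	9506	142135	27744	9967	49194	20417	11519	34171	0	111526	13598	144080	0	105052	85097	20493	6380	25541	33647	53611	12203	17025	21220	53398	49505	4418
k__Bacteria|p__Proteobacteria|g__Gen11	3384	26223	114291	56211	4158	8862	60239	24181	8183	18073	14654	9855	18993	6214	16375	0	42527	53493	37531	36151	15794	78860	60330	14780	4544	66814	29267	12239	12959	0
k__Bacteria|p__Actinobacteria|g__Gen12	34058	21576	64981	13377	55215	5372	12490	26765	33800	13475	15611	5801	4004	96480	42913	3760	9837	4618	31949	23936	19882	10596	97371	16868	45046	7625	7932	34955	11752	40208
k__Bacteria|p__Firmicutes|c__Clostridia|g__Gen13	35066	13130	33723	0	6368	42096	8925	0	7871	0	26760	18743	2179	4279	8379	30763	28778	6901	40299	0	0	3794	10090	3982	9876	33171	22708	13619	29133	14807
k__Bacteria|p__Bacteroidota|g__Gen14	28263	13522	32413	19417	0	38433	59078	7856	1231	24125	10224	58848	0	38417	12762	16385	0	0	85603	18281	48150	1943	19160	88950	104289	27408	51248	10270	41064	73489
k__Bacteria|p__Proteobacteria|g__Gen15	564	31085	99702	47798	6712	17394	5986	20970	25692	7552	1213	209403	199427	50202	0	44162	25105	16260	4625	57320	9527	10116	3384	45526	28948	65839	3439	3971	0	2845
k__Bacteria|p__Actinobacteria|g__Gen16	16163	10112	21258	0	2529	48697	0	8617	25332	28043	35576	9964	8782	20034	12830	0	15455	0	25468	26032	8599	3517	27782	13083	9017	9267	37164	11469	20271	10493
k__Bacteria|p__Firmicutes|c__Clostridia|g__Gen17	8061	18357	3583	11421	115476	6147	13768	4161	37251	51239	13392	33822	14021	5981	28173	38117	3705	107707	23246	25329	7777	7238	0	0	39476	13369	8215	13637	18374	3536
k__Bacteria|p__Bacteroidota|g__Gen18	36514	48075	61122	15100	33138	15312	2427	32753	35442	106963	49632	126204	17201	64689	0	50269	7754	20673	117821	48350	16509	18581	43882	0	251179	50510	62870	0	213767	34481
k__Bacteria|p__Proteobacteria|g__Gen19	2461	169283	25867	48823	7917	155993	24477	43840	6122	68241	21732	12736	24840	38812	25715	3465	2928	8687	0	14158	15468	2406	24817	13711	21908	28395	20211	0	48612	4138
k__Bacteria|p__Actinobacteria|g__Gen20	2785	5378	3227	32096	43381	48955	109942	0	55544	0	54217	20490	7827	58467	11879	76262	0	40278	10885	0	1764	8089	2473	10888	18175	0	10878	38825	26861	3782
k__Bacteria|p__Firmicutes|c__Clostridia|g__Gen21	62422	45217	79839	5245	12884	95579	8115	45640	9429	245381	50460	65950	4898	0	0	30756	4216	14790	94552	32697	0	55604	12971	10049	79432	5881	59750	7652	113120	13866
k__Bacteria|p__Bacteroidota|g__Gen22	0	36575	9822	0	15438	0	37801	59782	103084	13953	21996	80281	22227	13256	19364	14939	0	0	23485	19893	13841	28962	0	12560	0	10778	21013	14637	10239	13443
k__Bacteria|p__Proteobacteria|g__Gen23	57425	52547	35108	8639	4625	35860	7291	28169	20993	0	5464	0	21314	69213	15571	15306	14395	13264	0	73940	10362	5898	0	61799	16962	163107	18889	93830	17936	9253
k__Bacteria|p__Actinobacteria|g__Gen24	17682	34249	30434	18300	15113	50120	0	115293	18430	5489	10005	4150	7921	9152	21897	5026	6940	29209	19070	6777	2102	8633	3676	25209	7644	14470	7695	107892	21201	39655
k__Bacteria|p__Firmicutes|c__Clostridia|g__Gen25	30441	188950	0	89529	8453	0	17906	0	19047	29496	37435	25541	208351	0	24973	15117	37678	15023	24047	50506	15536	12197	54907	10379	19694	2873	16175	3618	13155	8688
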