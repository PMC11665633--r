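sample_id	condition	age_group
sample001	ctrl	sub1
sample002	ctrl	sub2
sample003	ctrl	sub1
sample004	ctrl	sub2
sample005	ctrl	sub1
sample006	ctrl	sub2
sample007	ctrl	sub1
sample008	ctrl	sub2
sample009	ctrl	sub1
sample010	ctrl	sub2
sample011	ctrl	sub1
sample012	ctrl	sub2
sample013	ctrl	sub1
sample014	ctrl	sub2
sample015	ctrl	sub1
sample016	case	sub1
sample017	case	sub2
sample018	case	sub1
sample019	case	sub2
sample020	case	sub1
sample021	case	sub2
sample022	case	sub1
sample023	case	sub2
sample024	case	sub1
sample025	case	sub2
sample026	case	sub1
sample027	case	sub2
sample028	case	sub1
sample029	case	sub2
sample030	case	sub1
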