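13	25200000	25210000	gene	MYC
13	25205000	25206000	UTR3	MYC
13	26905999	26908000	gene	GSDMC
13	26907212	26907215	CDS	GSDMC	frame=0;cds_seq=CAT
13	28304000	28305000	gene	LDH
13	28304327	28304330	CDS	LDH	frame=0;cds_seq=GAT
13	28304339	28304342	CDS	LDH	frame=0;cds_seq=GTT
13	29248000	29250000	gene	TMEM71
13	29249000	29249500	UTR5	TMEM71
13	29681000	29683000	gene	WISP1
13	29681900	29682400	UTR3	WISP1
13	29688000	29690000	gene	NDRG1
13	29689000	29689500	UTR3	NDRG1
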