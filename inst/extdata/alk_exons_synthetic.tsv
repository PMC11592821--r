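# gene_id=ALK transcript_id=ENST00000389048.8 gene_strand=- coords=0-based-half-open
chrom	start	end	exon_number
chr2	29921168	29921586	1
chr2	29899849	29899991	2
chr2	29893366	29893538	3
chr2	29890719	29891007	4
chr2	29875928	29876087	5
chr2	29848389	29848515	6
chr2	29822988	29823084	7
chr2	29800031	29800182	8
chr2	29798138	29798270	9
chr2	29787067	29787184	10
chr2	29757362	29757536	11
chr2	29731116	29731386	12
chr2	29712346	29712469	13
chr2	29694757	29694897	14
chr2	29677588	29677697	15
chr2	29653432	29653516	16
chr2	29624011	29624140	17
chr2	29594167	29594268	18
chr2	29591476	29591551	19
chr2	29570297	29570390	20
chr2	29554957	29555083	21
chr2	29533443	29533577	22
chr2	29530994	29531114	23
chr2	29524442	29524556	24
chr2	29516588	29516675	25
chr2	29508616	29508756	26
chr2	29495073	29495175	27
chr2	29477886	29478042	28
chr2	29468637	29470827	29
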