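# ABL1-BCR reciprocal-fusion subsegment coordinates in five CML cell lines
# (Ensembl rev 65 / GRCh37 positions). 5' partner: ABL1; 3' partner: BCR.
# published_group: subgroup labels reported for this fusion.
sample	gene_5p	gene_3p	start_5p	end_5p	start_3p	end_3p	published_group
BV-173	ABL1	BCR	133592718	133605045	23633005	23650421	1
K-562	ABL1	BCR	133592718	133605045	23633005	23650421	1
MEG-01	ABL1	BCR	133592718	133619550	23632191	23650421	1
EM-2	ABL1	BCR	133592718	133658924	23635685	23650421	2
LAMA-84	ABL1	BCR	133592718	133683574	23633005	23650421	2
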