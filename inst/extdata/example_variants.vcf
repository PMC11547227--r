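##fileformat=VCFv4.2
##INFO=<ID=AF_GNOMAD_EXOME,Number=1,Type=Float,Description="gnomAD exome allele frequency">
##INFO=<ID=AF_GNOMAD_GENOME,Number=1,Type=Float,Description="gnomAD genome allele frequency">
##INFO=<ID=AF_1000G,Number=1,Type=Float,Description="1000 Genomes allele frequency">
##INFO=<ID=GENE,Number=1,Type=String,Description="Gene symbol">
##INFO=<ID=EFFECT,Number=1,Type=String,Description="Predicted effect">
##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">
##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">
##contig=<ID=chr17,length=81195210>
##contig=<ID=chr8,length=146364022>
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	S1
chr17	7577539	.	G	A	.	PASS	GENE=TP53;EFFECT=deleterious	AD:DP	70,30:100
chr8	128750540	.	T	C	.	PASS	AF_GNOMAD_EXOME=0.0001;AF_GNOMAD_GENOME=0.001;AF_1000G=0.005	AD:DP	180,20:200
chr8	30000000	.	C	G	.	PASS	AF_GNOMAD_EXOME=0.25;AF_GNOMAD_GENOME=0.3;AF_1000G=0.28	AD:DP	250,240:490
chr17	41000000	.	A	T	.	PASS	.	AD:DP	0,0:0
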