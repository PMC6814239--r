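gene	description
APC	Tumour suppressor of the Wnt pathway; truncating variants cause autosomal dominant familial adenomatous polyposis and colorectal cancer.
ATM	Serine/threonine kinase of the DNA damage response; biallelic variants cause ataxia-telangiectasia, heterozygotes have elevated breast cancer risk.
BRCA1	E3 ubiquitin ligase in homologous recombination; autosomal dominant hereditary breast and ovarian cancer.
BRCA2	Homologous recombination mediator loading RAD51; autosomal dominant hereditary breast and ovarian cancer, pancreatic cancer.
CDH1	Epithelial cadherin; autosomal dominant hereditary diffuse gastric cancer.
MLH1	DNA mismatch repair; autosomal dominant Lynch syndrome with colorectal cancer predisposition.
MSH2	DNA mismatch repair; autosomal dominant Lynch syndrome with colorectal cancer predisposition.
MSH6	DNA mismatch repair component of MutS-alpha; Lynch syndrome, colorectal cancer.
PMS2	DNA mismatch repair endonuclease; Lynch syndrome, colorectal cancer.
PALB2	Partner and localizer of BRCA2; autosomal dominant breast cancer susceptibility.
PTEN	Phosphatidylinositol phosphatase; autosomal dominant hamartoma tumour syndromes.
RB1	Cell-cycle repressor; autosomal dominant retinoblastoma.
RET	Receptor tyrosine kinase; activating variants cause autosomal dominant multiple endocrine neoplasia type 2 and medullary thyroid cancer.
TP53	Genome-guardian transcription factor; autosomal dominant Li-Fraumeni syndrome.
STK11	Serine/threonine kinase; autosomal dominant Peutz-Jeghers syndrome.
VHL	E3 ligase substrate recognition; autosomal dominant von Hippel-Lindau syndrome, renal cancer.
ALDH2	Mitochondrial aldehyde dehydrogenase; common East Asian enzyme deficiency polymorphism.
MUC16	Large secreted mucin (CA-125 antigen); frequently mutated in exomes without disease association.
OR4F5	Olfactory receptor; common polymorphic variation.
SAMD11	Sterile alpha motif protein of uncertain disease relevance.
NOC2L	Nucleolar transcriptional repressor of uncertain disease relevance.
PLEKHN1	Pleckstrin homology domain protein of uncertain disease relevance.
KLHL17	Kelch-like family member of uncertain disease relevance.
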