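gene	disease_label	panel	validity	inheritance_modes	inheritance_qualifiers	allelic_requirement	mechanisms	variant_classes	constraints	narrative	references
CACNA1C	Timothy syndrome with isolated left ventricular hypertrophy	HCM_syndromic	Definitive	autosomal_dominant	typically_de_novo	monoallelic_autosomal	altered_gene_product_sequence	missense	[]	Reconstructed syndromic-HCM entry (synthetic stand-in row; see package documentation).	ClinGen:HCM
FLNC	filamin C-related hypertrophic cardiomyopathy	HCM_syndromic	Definitive	autosomal_dominant	incomplete_penetrance	monoallelic_autosomal	altered_gene_product_sequence	missense	[]	Missense-driven hypertrophic presentation, distinct from truncating-variant DCM. Reconstructed entry (synthetic stand-in row).	ClinGen:HCM
PRKAG2	PRKAG2 glycogen-storage cardiomyopathy	HCM_syndromic	Definitive	autosomal_dominant		monoallelic_autosomal	altered_gene_product_sequence	missense	[]	Reconstructed entry (synthetic stand-in row).	ClinGen:HCM
PTPN11	Noonan syndrome	HCM_syndromic	Definitive	autosomal_dominant	typically_de_novo	monoallelic_autosomal	altered_gene_product_sequence	missense	[]	Reconstructed entry (synthetic stand-in row).	ClinGen:HCM
PTPN11	Noonan syndrome with multiple lentigines	HCM_syndromic	Definitive	autosomal_dominant	typically_de_novo	monoallelic_autosomal	altered_gene_product_sequence	missense	[]	Reconstructed entry (synthetic stand-in row).	ClinGen:HCM
RAF1	RAF1-related Noonan syndrome	HCM_syndromic	Definitive	autosomal_dominant	typically_de_novo	monoallelic_autosomal	altered_gene_product_sequence	missense	[]	Reconstructed entry (synthetic stand-in row).	ClinGen:HCM
RIT1	RIT1-related Noonan syndrome	HCM_syndromic	Definitive	autosomal_dominant	typically_de_novo	monoallelic_autosomal	altered_gene_product_sequence	missense	[]	Reconstructed entry (synthetic stand-in row).	ClinGen:HCM
TTR	hereditary transthyretin amyloidosis	HCM_syndromic	Definitive	autosomal_dominant	age_related_onset	monoallelic_autosomal	altered_gene_product_sequence	missense	[]	Reconstructed entry (synthetic stand-in row).	ClinGen:HCM
FHL1	FHL1-related myopathy with left ventricular hypertrophy	HCM_syndromic	Definitive	x_linked		monoallelic_x_linked	decreased_gene_product_level;altered_gene_product_sequence	missense;nmd_truncating	[]	X-linked. Reconstructed entry (synthetic stand-in row).	ClinGen:HCM
GLA	Fabry disease	HCM_syndromic	Definitive	x_linked		monoallelic_x_linked	absent_gene_product_level;altered_gene_product_sequence	missense;nmd_truncating;structural_exon_deletion	[]	X-linked. Reconstructed entry (synthetic stand-in row).	ClinGen:HCM
LAMP2	Danon disease	HCM_syndromic	Definitive	x_linked		monoallelic_x_linked	absent_gene_product_level;altered_gene_product_sequence	missense;nmd_truncating	[]	X-linked. Reconstructed entry (synthetic stand-in row).	ClinGen:HCM
DES	desmin-related myofibrillar myopathy with cardiac hypertrophy	HCM_syndromic	Definitive	autosomal_dominant		monoallelic_autosomal	decreased_gene_product_level;altered_gene_product_sequence	missense;nmd_truncating	[]	Reconstructed entry (synthetic stand-in row).	ClinGen:HCM
BAG3	BAG3-related myofibrillar myopathy	HCM_syndromic	Definitive	autosomal_dominant	typically_de_novo	monoallelic_autosomal	decreased_gene_product_level;altered_gene_product_sequence	missense;nmd_truncating	[]	Reconstructed entry (synthetic stand-in row).	ClinGen:HCM
GAA	Pompe disease	HCM_syndromic	Definitive	autosomal_recessive		biallelic_autosomal	absent_gene_product_level;altered_gene_product_sequence	missense;nmd_truncating	[]	Reconstructed entry (synthetic stand-in row).	ClinGen:HCM
MYH6	hypertrophic cardiomyopathy	HCM	Limited				 	 	[]	Gene-disease validity below Moderate; inheritance and mechanism terms are not speculated. Representative stand-in for the unestablished-pair listing.	ClinGen:HCM
ANK2	long QT syndrome	LQTS	Disputed				 	 	[]	Gene-disease validity disputed; carried for completeness only. Representative stand-in for the unestablished-pair listing.	ClinGen:LQTS
KCNE2	long QT syndrome	LQTS	Limited				 	 	[]	Gene-disease validity below Moderate; carried for completeness only. Representative stand-in for the unestablished-pair listing.	ClinGen:LQTS
CTNNA3	arrhythmogenic right ventricular cardiomyopathy	ARVC	Limited				 	 	[]	Gene-disease validity below Moderate; carried for completeness only. Representative stand-in for the unestablished-pair listing.	ClinGen:ARVC
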