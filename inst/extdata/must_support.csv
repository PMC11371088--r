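kind,field
CancerPatient,birth_date
CancerPatient,sex
CancerPatient,race
CancerPatient,ethnicity
GenomicsReport,test_date
GenomicsReport,specimen_ref
GenomicsReport,result_refs
GenomicVariant,gene
GenomicVariant,dna_change
GenomicVariant,dna_change_type
GenomicVariant,genomic_source_class
GenomicVariant,amino_acid_change
GenomicVariant,allelic_frequency
GenomicVariant,clinical_significance
GenomicRegionStudied,genes
GenomicSpecimen,specimen_type
GenomicSpecimen,collected_date
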