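source_table,source_column,profile_kind,field_path,code_system,value_map,disposition
patients,patient_id,CancerPatient,resource_id,,,identifier
patients,birth_date,CancerPatient,birth_date,,,field
patients,sex,CancerPatient,sex,administrative-gender,sex,field
patients,race,CancerPatient,race,cdc-race-ethnicity,race,field
patients,ethnicity,CancerPatient,ethnicity,cdc-race-ethnicity,ethnicity,field
diagnoses,patient_id,CancerPatient,subject,,,identifier
diagnoses,phecode,CancerPatient,extension:diagnosis,phecode,,extension
diagnoses,label,CancerPatient,extension:diagnosis,phecode,,extension
diagnoses,onset_date,CancerPatient,extension:diagnosis-onset,,,extension
reports,report_id,GenomicsReport,resource_id,,,identifier
reports,patient_id,GenomicsReport,subject,,,identifier
reports,specimen_id,GenomicsReport,specimen_ref,,,identifier
reports,test_date,GenomicsReport,test_date,,,field
reports,regions_studied,GenomicRegionStudied,genes,hgnc,gene,field
variants,report_id,GenomicVariant,resource_id,,,identifier
variants,gene_symbol,GenomicVariant,gene,hgnc,gene,field
variants,dna_change,GenomicVariant,dna_change,hgvs,,field
variants,dna_change_type,GenomicVariant,dna_change_type,sequence-ontology,dna_change_type,field
variants,genomic_source_class,GenomicVariant,genomic_source_class,loinc,genomic_source_class,field
variants,amino_acid_change,GenomicVariant,amino_acid_change,hgvs,,field
variants,allelic_frequency,GenomicVariant,allelic_frequency,,,field
variants,clinical_significance,GenomicVariant,clinical_significance,loinc,clinical_significance,field
(derived),variants.report_id,GenomicsReport,result_refs,,,derived
specimens,specimen_id,GenomicSpecimen,resource_id,,,identifier
specimens,patient_id,GenomicSpecimen,subject,,,identifier
specimens,specimen_type,GenomicSpecimen,specimen_type,v2-0487,specimen_type,field
specimens,collected_date,GenomicSpecimen,collected_date,,,field
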