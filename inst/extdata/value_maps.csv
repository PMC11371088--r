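map,source,code,display
sex,F,female,Female
sex,M,male,Male
sex,O,other,Other
sex,U,unknown,Unknown
race,W,2106-3,White
race,B,2054-5,Black or African American
race,A,2028-9,Asian
race,N,1002-5,American Indian or Alaska Native
race,P,2076-8,Native Hawaiian or Other Pacific Islander
race,O,2131-1,Other Race
ethnicity,H,2135-2,Hispanic or Latino
ethnicity,N,2186-5,Not Hispanic or Latino
dna_change_type,SNV,SO:0001483,SNV
dna_change_type,DEL,SO:0000159,deletion
dna_change_type,INS,SO:0000667,insertion
dna_change_type,DUP,SO:1000035,duplication
dna_change_type,DELINS,SO:1000032,delins
genomic_source_class,somatic,LA6684-0,Somatic
genomic_source_class,germline,LA6683-2,Germline
clinical_significance,PATHOGENIC,LA6668-3,Pathogenic
clinical_significance,LIKELY_PATHOGENIC,LA26332-9,Likely pathogenic
clinical_significance,VUS,LA26333-7,Uncertain significance
clinical_significance,LIKELY_BENIGN,LA26334-5,Likely benign
clinical_significance,BENIGN,LA6675-8,Benign
specimen_type,TUMOR,TUMOR,Tumor tissue
specimen_type,BLOOD,BLD,Whole blood
specimen_type,TISSUE,TISS,Tissue
specimen_type,SALIVA,SAL,Saliva
specimen_type,BONE_MARROW,BON,Bone marrow
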