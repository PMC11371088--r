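phecode,tcga_label
145,HNSC
150,ESCA
151,STAD
153,COAD
154,READ
155,LIHC
155.1,CHOL
157,PAAD
158,MESO
164,THYM
165.1,LUAD
165.2,LUSC
170,SARC
172.11,SKCM
174.1,BRCA
180,CESC
182,UCEC
182.2,UCS
183,OV
185,PRAD
186,TGCT
188,BLCA
189.1,KIRC
189.12,KIRP
189.13,KICH
190,UVM
191,GBM
191.1,LGG
193,THCA
194.1,ACC
194.2,PCPG
202.2,DLBC
204.1,LAML
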