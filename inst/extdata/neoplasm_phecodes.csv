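phecode,label
145,Cancer of head and neck
150,Cancer of esophagus
151,Cancer of stomach
153,Colorectal cancer
154,Cancer of rectum
155,Cancer of liver and intrahepatic bile duct
155.1,Cancer of bile duct
157,Pancreatic cancer
158,Mesothelioma
164,Cancer of thymus
165.1,Cancer of bronchus; lung
165.2,Squamous cell carcinoma of lung
170,Cancer of bone and connective tissue
172.11,Melanoma of skin
174.1,Breast cancer
180,Cervical cancer
182,Cancer of uterus and endometrium
182.2,Uterine carcinosarcoma
183,Ovarian cancer
185,Prostate cancer
186,Cancer of testis
188,Cancer of bladder
189.1,Renal cell carcinoma
189.12,Papillary renal cell carcinoma
189.13,Chromophobe renal cell carcinoma
190,Uveal melanoma
191,Glioblastoma
191.1,Lower grade glioma
193,Thyroid cancer
194.1,Adrenocortical carcinoma
194.2,Pheochromocytoma and paraganglioma
202.2,Diffuse large B-cell lymphoma
204.1,Acute myeloid leukemia
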