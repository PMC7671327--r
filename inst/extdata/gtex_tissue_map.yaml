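# Best-effort mapping of the 54 GTEx v8 collection sites to 33 tissue
# categories. Cerebellum (and cerebellar hemisphere) is kept separate from
# the other brain regions, and the two cultured cell lines remain their
# own categories; edit freely and pass the edited file to
# assign_tissue_categories().
"Adipose - Subcutaneous": adipose
"Adipose - Visceral (Omentum)": adipose
"Adrenal Gland": adrenal_gland
"Artery - Aorta": artery
"Artery - Coronary": artery
"Artery - Tibial": artery
"Bladder": bladder
"Brain - Amygdala": brain
"Brain - Anterior cingulate cortex (BA24)": brain
"Brain - Caudate (basal ganglia)": brain
"Brain - Cerebellar Hemisphere": cerebellum
"Brain - Cerebellum": cerebellum
"Brain - Cortex": brain
"Brain - Frontal Cortex (BA9)": brain
"Brain - Hippocampus": brain
"Brain - Hypothalamus": brain
"Brain - Nucleus accumbens (basal ganglia)": brain
"Brain - Putamen (basal ganglia)": brain
"Brain - Spinal cord (cervical c-1)": brain
"Brain - Substantia nigra": brain
"Breast - Mammary Tissue": breast
"Cells - Cultured fibroblasts": fibroblasts
"Cells - EBV-transformed lymphocytes": lymphocytes
"Cervix - Ectocervix": cervix_uteri
"Cervix - Endocervix": cervix_uteri
"Colon - Sigmoid": colon
"Colon - Transverse": colon
"Esophagus - Gastroesophageal Junction": esophagus
"Esophagus - Mucosa": esophagus
"Esophagus - Muscularis": esophagus
"Fallopian Tube": fallopian_tube
"Heart - Atrial Appendage": heart
"Heart - Left Ventricle": heart
"Kidney - Cortex": kidney
"Kidney - Medulla": kidney
"Liver": liver
"Lung": lung
"Minor Salivary Gland": salivary_gland
"Muscle - Skeletal": muscle
"Nerve - Tibial": nerve
"Ovary": ovary
"Pancreas": pancreas
"Pituitary": pituitary
"Prostate": prostate
"Skin - Not Sun Exposed (Suprapubic)": skin
"Skin - Sun Exposed (Lower leg)": skin
"Small Intestine - Terminal Ileum": small_intestine
"Spleen": spleen
"Stomach": stomach
"Testis": testis
"Thyroid": thyroid
"Uterus": uterus
"Vagina": vagina
"Whole Blood": blood
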