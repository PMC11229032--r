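# Default tumor -> control-tissue assignment (editable).
# One line per TCGA tumor code; second column is the comma-separated list of
# GTEx primary-site names pooled with the tumor's adjacent normals as the
# control group. An empty second column means adjacent normals only.
# Review these assignments before production use; they follow the usual
# TCGA-to-GTEx tissue pairing and can be freely edited.
ACC	Adrenal Gland
BLCA	Bladder
BRCA	Breast
CESC	Cervix Uteri
CHOL	Liver
COAD	Colon
DLBC	Blood
ESCA	Esophagus
GBM	Brain
HNSC
KICH	Kidney
KIRC	Kidney
KIRP	Kidney
LAML	Bone Marrow
LGG	Brain
LIHC	Liver
LUAD	Lung
LUSC	Lung
MESO
OV	Ovary
PAAD	Pancreas
PCPG	Adrenal Gland
PRAD	Prostate
READ	Colon
SARC	Adipose Tissue,Muscle
SKCM	Skin
STAD	Stomach
TGCT	Testis
THCA	Thyroid
THYM
UCEC	Uterus
UCS	Uterus
UVM
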