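name,ic50_uM,label,activity_class,reference,ic50_source
picropodophyllin,0.04,active,MOST_ACTIVE,lit-curated,reported
NVP-AEW541,0.15,active,MOST_ACTIVE,lit-curated,reconstructed
BMS-754807,0.25,active,MOST_ACTIVE,lit-curated,reconstructed
NVP-ADW742,0.4,active,MOST_ACTIVE,lit-curated,reconstructed
BMS-536924,0.8,active,MODERATELY_ACTIVE,lit-curated,reconstructed
AG1024,1.2,active,MODERATELY_ACTIVE,lit-curated,reconstructed
GSK1904529A,1.8,active,MODERATELY_ACTIVE,lit-curated,reconstructed
linsitinib,2.4,active,MODERATELY_ACTIVE,lit-curated,reconstructed
AG538,3.2,active,MODERATELY_ACTIVE,lit-curated,reconstructed
I-OMe-AG538,4.0,active,MODERATELY_ACTIVE,lit-curated,reconstructed
BMS-554417,5.5,active,MODERATELY_ACTIVE,lit-curated,reconstructed
PQ401,7.5,active,MODERATELY_ACTIVE,lit-curated,reconstructed
nordihydroguaiaretic-acid,9.0,active,MODERATELY_ACTIVE,lit-curated,reconstructed
XL228,11.0,active,MODERATELY_ACTIVE,lit-curated,reconstructed
KW-2450,13.0,active,MODERATELY_ACTIVE,lit-curated,reconstructed
INSM-18,16.0,active,MODERATELY_ACTIVE,lit-curated,reconstructed
TAE226,19.0,active,MODERATELY_ACTIVE,lit-curated,reconstructed
genistein,28.0,active,LESS_ACTIVE,lit-curated,reconstructed
quercetin,35.0,active,LESS_ACTIVE,lit-curated,reconstructed
AGL-2263,45.0,active,LESS_ACTIVE,lit-curated,reconstructed
apigenin,55.0,active,LESS_ACTIVE,lit-curated,reconstructed
daidzein,100.0,inactive,INACTIVE,lit-curated,reconstructed
biochanin-A,200.0,inactive,INACTIVE,lit-curated,reconstructed
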