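Gene,Non-unique Gene name,Annotation,No. isolates,No. sequences,Avg sequences per isolate,Genome Fragment,Order within Fragment,Accessory Fragment,Accessory Order with Fragment,QC,Min group size nuc,Max group size nuc,Avg group size nuc,gA,gB,gC
groL,,chaperonin,3,3,1,1,1,,,,1600,1600,1600,gA_00001,gB_00001,gC_00001
dnaK,,chaperone,2,2,1,1,2,,,,1900,1900,1900,gA_00002,,gC_00002
abcT,,ABC transporter,1,1,1,2,1,,,,900,900,900,,gB_00003,
lacZ,,beta-galactosidase,2,2,1,2,2,,,,3000,3000,3000,gA_00003,gB_00004,
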