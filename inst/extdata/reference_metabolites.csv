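name,ref_mz,ref_rt,msi_level,source
methionine,150.0583,2.1,1,venom metabolome survey (illustrative subset)
citric acid,193.0343,2.8,1,venom metabolome survey (illustrative subset)
tryptophan,205.0972,6.2,2,HMDB (illustrative subset)
deoxyribose 5-monophosphate,215.0315,,-,HMDB (illustrative subset)
pENW,430.1721,,2,venom metabolome survey (illustrative subset)
d9-caffeine (internal standard),204.1500,7.5,1,spiked standard
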