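term,df,sumsq
Species,5,409.7
Media,1,1.0
Co-Culture,1,5.4
Strain in species,19,143.4
Species:Media,5,145.2
Species:Co-culture,5,6.2
Strain in Species:Media,19,20.2
Strain in Species:Co-culture,19,44.7
Residuals,425,50.4
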