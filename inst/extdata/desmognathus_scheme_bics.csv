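# Published scheme-comparison example: best-family EDDA BIC per taxonomic
# hypothesis for the three-species dusky-salamander dataset (BICs as
# printed, integer precision; maximize-BIC convention).
scheme,K,BIC
conanti | pascagoula-valentinei,2,6681
conanti | pascagoula | valentinei,3,6670
conanti-pascagoula-valentinei,1,6394
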