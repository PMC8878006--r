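name,formula,adduct
L-tryptophan,C11H12N2O2,[M+H]+
Indoleacrylic acid,C11H9NO2,[M+H]+
Tryptamine,C10H12N2,[M+H]+
5-methoxy-indolelactic acid,C11H11NO3,[M+H]+
2-octenoylcarnitine,C15H27NO4,[M+H]+
L-phenylalanyl-L-hydroxyproline,C14H18N2O4,[M+H]+
Decanoylcarnitine,C17H33NO4,[M+H]+
9-decenoylcarnitine,C17H31NO4,[M+H]+
L-glutamine,C5H10N2O3,[M+H]+
L-glutamine dimer,C5H10N2O3,[2M+H]+
6-keto-decanoylcarnitine,C17H31NO5,[M+H]+
Indole,C8H7N,[M+H]+
Phenylacetic acid,C8H8O2,[M+H]+
Estrone sulfate,C18H22O5S,[M-H]-
Sebacic acid,C10H18O4,[M-H]-
Hydroxyhippuric acid,C9H9NO4,[2M-H]-
Hippuric acid,C9H9NO3,[2M-H]-
Tiglylglycine,C7H11NO3,[M+H]+
Uric acid,C5H4N4O3,[M-H]-
Hydroxybutyric acid,C4H8O3,[M-H]-
Threonic acid,C4H8O5,[M-H]-
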