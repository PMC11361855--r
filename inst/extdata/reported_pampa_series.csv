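peptide,publication_order,log10_permeability
cyclosporin_A,1,-5.01
cyclosporin_A,2,-6.2
cyclosporin_A,3,-6.15
cyclosporin_A,4,-5.71
cyclosporin_A,5,-5.72
1NMe3,1,-4.5
1NMe3,2,-4.4
1NMe3,3,-6
1NMe3,4,-6.24
1NMe3,5,-6.4
1NMe3,6,-5.52
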