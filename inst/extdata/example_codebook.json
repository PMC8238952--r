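[{"name":"Fstl1","barcode":"0101000000101000","is_blank":false},{"name":"Pdgfra","barcode":"1010000000001010","is_blank":false},{"name":"Notch3","barcode":"0010001100010000","is_blank":false},{"name":"Flt4","barcode":"0001111000000000","is_blank":false},{"name":"Stab2","barcode":"1000001001010000","is_blank":false},{"name":"Lyve1","barcode":"0000001010000101","is_blank":false},{"name":"Alb","barcode":"0001010101000000","is_blank":false},{"name":"Afp","barcode":"0011000100000010","is_blank":false},{"name":"Adgre1","barcode":"0001100000011000","is_blank":false},{"name":"Csf1r","barcode":"0010110000000001","is_blank":false},{"name":"Pf4","barcode":"0110000000011000","is_blank":false},{"name":"Itga2b","barcode":"0010100100000100","is_blank":false},{"name":"Mpo","barcode":"0110000000000110","is_blank":false},{"name":"Elane","barcode":"0001100001100000","is_blank":false},{"name":"Gata1","barcode":"0000000100101100","is_blank":false},{"name":"Klf1","barcode":"0010001001000100","is_blank":false},{"name":"Hba-a1","barcode":"0101000010000010","is_blank":false},{"name":"Gypa","barcode":"0010000000001101","is_blank":false},{"name":"Mecom","barcode":"0000000100110010","is_blank":false},{"name":"Kit","barcode":"0000101010100000","is_blank":false},{"name":"Blank-1","barcode":"0000000010101010","is_blank":true},{"name":"Blank-2","barcode":"0001001000010010","is_blank":true}]
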