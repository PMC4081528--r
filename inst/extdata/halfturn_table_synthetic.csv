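segment,label,w_RM_um,w_OC_um,l_um
0,hook,NA,NA,2000
1,I,427.094009130718,394.531600179292,3400
2,II,491.158110500326,438.368444643658,3000
3,III,555.222211869934,482.205289108023,2600
4,IV,619.286313239542,526.042133572389,2300
5,V,683.35041460915,569.878978036755,2000
6,VI,747.414515978757,613.715822501121,1600
7,VII,822.155967576633,668.511878081578,1200
8,VIII,907.574769402777,723.307933662035,800
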