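"case_id","reason"
"C0001","none"
"C0002","none"
"C0003","none"
"C0004","none"
"C0005","insufficient_material"
"C0006","none"
"C0007","none"
"C0008","none"
"C0009","none"
"C0010","none"
"C0011","none"
"C0012","none"
"C0013","none"
"C0014","insufficient_material"
"C0015","none"
"C0016","misclassified"
"C0017","none"
"C0018","none"
"C0019","none"
"C0020","none"
"C0021","none"
"C0022","none"
"C0023","misclassified"
"C0024","none"
"C0025","none"
"C0026","misclassified"
"C0027","none"
"C0028","none"
"C0029","misclassified"
"C0030","none"
"C0031","none"
"C0032","none"
"C0033","none"
"C0034","none"
"C0035","none"
"C0036","poor_quality"
"C0037","none"
"C0038","none"
"C0039","none"
"C0040","none"
"C0041","insufficient_material"
"C0042","none"
"C0043","misclassified"
"C0044","none"
"C0045","none"
"C0046","none"
"C0047","none"
"C0048","none"
"C0049","none"
"C0050","misclassified"
"C0051","none"
"C0052","none"
"C0053","none"
"C0054","none"
"C0055","none"
"C0056","none"
"C0057","none"
"C0058","none"
"C0059","misclassified"
"C0060","insufficient_material"
"C0061","none"
"C0062","none"
"C0063","none"
"C0064","none"
"C0065","none"
"C0066","poor_quality"
"C0067","insufficient_material"
"C0068","misclassified"
"C0069","none"
"C0070","insufficient_material"
"C0071","poor_quality"
"C0072","none"
"C0073","none"
"C0074","none"
"C0075","poor_quality"
"C0076","none"
"C0077","insufficient_material"
"C0078","none"
"C0079","none"
"C0080","none"
"C0081","none"
"C0082","none"
"C0083","none"
"C0084","none"
"C0085","none"
"C0086","none"
"C0087","misclassified"
"C0088","none"
"C0089","none"
"C0090","misclassified"
"C0091","none"
"C0092","poor_quality"
"C0093","none"
"C0094","none"
"C0095","none"
"C0096","none"
"C0097","none"
"C0098","none"
"C0099","none"
"C0100","none"
"C0101","poor_quality"
"C0102","insufficient_material"
"C0103","none"
"C0104","none"
"C0105","none"
"C0106","none"
"C0107","none"
"C0108","none"
"C0109","insufficient_material"
"C0110","none"
"C0111","none"
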