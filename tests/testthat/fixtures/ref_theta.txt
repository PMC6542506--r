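0.78223459096625447, 0.57546308171004057, 0.012372695375233889, 0.60797915980219841, -0.89497358119115233, 0.59058568207547069, -0.4942466733045876, 0.84736809367313981, -0.4346008412539959, 0.59404461551457644, -0.63288628123700619, 0.85045837284997106, 0.86419579386711121, -0.62940388871356845, -0.1091899792663753, -0.28618448926135898, 0.086227771826088428, -0.97110094409435987, -0.69943153718486428, -0.26366439368575811, -0.34349516313523054, -0.74033941794186831
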