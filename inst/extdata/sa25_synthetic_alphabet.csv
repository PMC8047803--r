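"letter","d13","d14","d24","dihedral"
"a",0.488519,0.339132,0.488519,0.628319
"b",0.488519,0.654341,0.488519,1.884956
"c",0.488519,0.78848,0.488519,3.141593
"d",0.488519,0.654341,0.488519,-1.884956
"e",0.488519,0.339132,0.488519,-0.628319
"f",0.582194,0.561791,0.582194,0.628319
"g",0.582194,0.792944,0.582194,1.884956
"h",0.582194,0.906807,0.582194,3.141593
"i",0.582194,0.792944,0.582194,-1.884956
"j",0.582194,0.561791,0.582194,-0.628319
"k",0.658179,0.786745,0.658179,0.628319
"l",0.658179,0.927973,0.658179,1.884956
"m",0.658179,1.005385,0.658179,3.141593
"n",0.658179,0.927973,0.658179,-1.884956
"o",0.658179,0.786745,0.658179,-0.628319
"p",0.714166,0.973964,0.714166,0.628319
"q",0.714166,1.0402,0.714166,1.884956
"r",0.714166,1.079105,0.714166,3.141593
"s",0.714166,1.0402,0.714166,-1.884956
"t",0.714166,0.973964,0.714166,-0.628319
"u",0.748454,1.097111,0.748454,0.628319
"v",0.748454,1.114192,0.748454,1.884956
"w",0.748454,1.124618,0.748454,3.141593
"x",0.748454,1.114192,0.748454,-1.884956
"y",0.748454,1.097111,0.748454,-0.628319
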