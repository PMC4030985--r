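"","ALA","ARG","ASN","ASP","CYS","GLN","GLU","GLY","HIS","ILE","LEU","LYS","MET","PHE","PRO","SER","THR","TRP","TYR","VAL"
"ALA",-0.508889,0.191111,0.08,0.08,-0.586667,0.08,0.08,-0.264444,0.046667,-0.808889,-0.731111,0.124444,-0.52,-0.62,-0.131111,-0.22,-0.231111,-0.208889,-0.164444,-0.775556
"ARG",0.191111,0.891111,0.78,0.78,0.113333,0.78,0.78,0.435556,0.746667,-0.108889,-0.031111,0.824444,0.18,0.08,0.568889,0.48,0.468889,0.491111,0.535556,-0.075556
"ASN",0.08,0.78,0.668889,0.668889,0.002222,0.668889,0.668889,0.324444,0.635556,-0.22,-0.142222,0.713333,0.068889,-0.031111,0.457778,0.368889,0.357778,0.38,0.424444,-0.186667
"ASP",0.08,0.78,0.668889,0.668889,0.002222,0.668889,0.668889,0.324444,0.635556,-0.22,-0.142222,0.713333,0.068889,-0.031111,0.457778,0.368889,0.357778,0.38,0.424444,-0.186667
"CYS",-0.586667,0.113333,0.002222,0.002222,-0.664444,0.002222,0.002222,-0.342222,-0.031111,-0.886667,-0.808889,0.046667,-0.597778,-0.697778,-0.208889,-0.297778,-0.308889,-0.286667,-0.242222,-0.853333
"GLN",0.08,0.78,0.668889,0.668889,0.002222,0.668889,0.668889,0.324444,0.635556,-0.22,-0.142222,0.713333,0.068889,-0.031111,0.457778,0.368889,0.357778,0.38,0.424444,-0.186667
"GLU",0.08,0.78,0.668889,0.668889,0.002222,0.668889,0.668889,0.324444,0.635556,-0.22,-0.142222,0.713333,0.068889,-0.031111,0.457778,0.368889,0.357778,0.38,0.424444,-0.186667
"GLY",-0.264444,0.435556,0.324444,0.324444,-0.342222,0.324444,0.324444,-0.02,0.291111,-0.564444,-0.486667,0.368889,-0.275556,-0.375556,0.113333,0.024444,0.013333,0.035556,0.08,-0.531111
"HIS",0.046667,0.746667,0.635556,0.635556,-0.031111,0.635556,0.635556,0.291111,0.602222,-0.253333,-0.175556,0.68,0.035556,-0.064444,0.424444,0.335556,0.324444,0.346667,0.391111,-0.22
"ILE",-0.808889,-0.108889,-0.22,-0.22,-0.886667,-0.22,-0.22,-0.564444,-0.253333,-1.108889,-1.031111,-0.175556,-0.82,-0.92,-0.431111,-0.52,-0.531111,-0.508889,-0.464444,-1.075556
"LEU",-0.731111,-0.031111,-0.142222,-0.142222,-0.808889,-0.142222,-0.142222,-0.486667,-0.175556,-1.031111,-0.953333,-0.097778,-0.742222,-0.842222,-0.353333,-0.442222,-0.453333,-0.431111,-0.386667,-0.997778
"LYS",0.124444,0.824444,0.713333,0.713333,0.046667,0.713333,0.713333,0.368889,0.68,-0.175556,-0.097778,0.757778,0.113333,0.013333,0.502222,0.413333,0.402222,0.424444,0.468889,-0.142222
"MET",-0.52,0.18,0.068889,0.068889,-0.597778,0.068889,0.068889,-0.275556,0.035556,-0.82,-0.742222,0.113333,-0.531111,-0.631111,-0.142222,-0.231111,-0.242222,-0.22,-0.175556,-0.786667
"PHE",-0.62,0.08,-0.031111,-0.031111,-0.697778,-0.031111,-0.031111,-0.375556,-0.064444,-0.92,-0.842222,0.013333,-0.631111,-0.731111,-0.242222,-0.331111,-0.342222,-0.32,-0.275556,-0.886667
"PRO",-0.131111,0.568889,0.457778,0.457778,-0.208889,0.457778,0.457778,0.113333,0.424444,-0.431111,-0.353333,0.502222,-0.142222,-0.242222,0.246667,0.157778,0.146667,0.168889,0.213333,-0.397778
"SER",-0.22,0.48,0.368889,0.368889,-0.297778,0.368889,0.368889,0.024444,0.335556,-0.52,-0.442222,0.413333,-0.231111,-0.331111,0.157778,0.068889,0.057778,0.08,0.124444,-0.486667
"THR",-0.231111,0.468889,0.357778,0.357778,-0.308889,0.357778,0.357778,0.013333,0.324444,-0.531111,-0.453333,0.402222,-0.242222,-0.342222,0.146667,0.057778,0.046667,0.068889,0.113333,-0.497778
"TRP",-0.208889,0.491111,0.38,0.38,-0.286667,0.38,0.38,0.035556,0.346667,-0.508889,-0.431111,0.424444,-0.22,-0.32,0.168889,0.08,0.068889,0.091111,0.135556,-0.475556
"TYR",-0.164444,0.535556,0.424444,0.424444,-0.242222,0.424444,0.424444,0.08,0.391111,-0.464444,-0.386667,0.468889,-0.175556,-0.275556,0.213333,0.124444,0.113333,0.135556,0.18,-0.431111
"VAL",-0.775556,-0.075556,-0.186667,-0.186667,-0.853333,-0.186667,-0.186667,-0.531111,-0.22,-1.075556,-0.997778,-0.142222,-0.786667,-0.886667,-0.397778,-0.486667,-0.497778,-0.475556,-0.431111,-1.042222
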