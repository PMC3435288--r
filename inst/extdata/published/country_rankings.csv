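country,phi,relative_phi
Taiwan,0.639,9.054
Republic of Korea,0.594,8.413
Egypt,0.155,2.197
Spain,0.096,1.355
Saudi Arabia,0.067,0.953
Sri Lanka,0.066,0.939
India,0.022,0.315
Yemen,0.013,0.186
Turkey,0.012,0.168
Pakistan,0.009,0.121
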