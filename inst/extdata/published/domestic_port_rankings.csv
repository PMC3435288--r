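port,phi,relative_phi
Melbourne,0.547,8.921
Botany Bay,0.398,6.487
Brisbane,0.390,6.369
Bell Bay,0.217,3.537
Fremantle,0.154,2.517
Adelaide,0.095,1.548
Burnie,0.050,0.808
Sydney,0.026,0.418
Hobart,0.014,0.225
Newcastle,0.003,0.047
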