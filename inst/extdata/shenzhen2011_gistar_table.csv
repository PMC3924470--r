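cluster_type,area_id,observed,expected,sr,gi_p,gi_z
hot,Fubao,107,107.21,1.00,0.01,2.55
hot,Futian,248,247.83,1.00,0.08,1.74
hot,Nanyuan,109,113.97,0.96,0.08,1.77
hot,Shatou,134,226.66,0.59,0.06,1.90
hot,Guiyuan,152,82.59,1.84,0.07,1.82
hot,Kuiyong,176,61.34,2.87,0.02,2.34
hot,Nanao,51,19.05,2.68,0.03,2.14
hot,Dapeng,87,46.44,1.87,0.009,3.15
cold,Guannan,370,453.96,0.82,0.08,-1.77
cold,Shajing,287,531.41,0.54,0.09,-1.72
cold,Dalang,147,279.45,0.53,0.05,-1.94
cold,Longhua,148,366.27,0.40,0.02,-2.39
cold,Pinghu,219,229.34,0.95,0.06,-1.91
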