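cluster,area_id,observed,expected,relative_risk,p_value
primary,Meilin,212,152.13,2.69,0.0001
primary,Lianhua,576,163.28,2.69,0.0001
primary,Xiangmihu,216,82.43,2.69,0.0001
secondary2,Dapeng,87,46.44,2.52,0.0001
secondary2,Kuiyong,176,61.34,2.52,0.0001
secondary2,Nanao,51,19.05,2.52,0.0001
secondary3,Zhaoshang,224,80.12,2.84,0.0001
secondary4,Liantang,82,84.40,1.44,0.0001
secondary4,Donghu,166,83.55,1.44,0.0001
secondary4,Huangbei,170,112.03,1.44,0.0001
secondary4,Cuizhu,160,115.91,1.44,0.0001
secondary4,Dongxiao,46,103.72,1.44,0.0001
secondary4,Dongmen,153,91.46,1.44,0.0001
secondary4,Sungang,94,63.47,1.44,0.0001
secondary4,Nanhu,157,90.83,1.44,0.0001
secondary4,Guiyuan,152,82.59,1.44,0.0001
secondary5,Shiyan,444,248.76,1.82,0.0001
secondary6,Pingdi,142,95.70,1.49,0.0014
secondary7,Gongming,400,320.10,1.26,0.0018
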