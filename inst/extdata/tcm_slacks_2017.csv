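province,slack_institutions,slack_beds,slack_staff,slack_outpatient_visits,slack_discharged_patients
Beijing,0,0,0,0,0
Tianjin,0,-2948.680,0,14.631,0
Hebei,-243094.171,0,-485.968,6.912,0
Shanxi,0,0,-1552.857,0,0
Inner Mongolia,0,0,-1578.506,0,0
Liaoning,0,0,-882.423,0,0
Jilin,0,0,-710.180,0,0
Heilongjiang,0,-608.632,-331.049,0,0
Shanghai,0,0,0,0,0
Jiangsu,-624295.457,-13344.929,0,0,0
Zhejiang,0,0,0,0,0
Anhui,-528760.717,-12417.236,0,0,0
Fujian,0,0,-160.221,0,0
Jiangxi,-226022.560,-3264.524,0,0,0
Shandong,-608706.100,-17189.485,-17.937,0,0
Henan,-758414.024,-21243.353,0,0,0
Hubei,-536501.730,-5417.382,0,0,0
Hunan,-762269.571,-19295.378,-412.403,0,0
Guangdong,0,0,0,0,0
Guangxi,-172828.226,-5120.625,0,0,0
Hainan,0,-680.028,-9.715,0,0
Chongqing,0,0,-813.431,0,0
Sichuan,-814776.018,-4647.753,-3037.551,0,0
Guizhou,-222670.741,-5438.150,0,0,0
Yunnan,-125135.601,-1868.266,0,0,0
Tibet,0,0,0,0,0
Shaanxi,-78967.758,-11919.417,-166.413,0,0
Gansu,-27777.106,0,-440.365,0,0
Qinghai,0,0,0,0,0
Ningxia,0,0,0,0,0
Xinjiang,0,0,0,0,0
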