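province,effch,techch,pech,sech,tfpch
Beijing,1.000,0.942,1.000,1.000,0.942
Tianjin,0.999,0.956,1.001,0.998,0.954
Hebei,1.036,0.945,1.023,1.013,0.979
Shanxi,1.024,0.953,1.013,1.010,0.975
Inner Mongolia,0.989,0.967,1.005,0.984,0.957
Liaoning,0.997,0.955,0.989,1.007,0.952
Jilin,1.013,0.951,1.002,1.010,0.964
Heilongjiang,0.987,0.953,0.982,1.005,0.941
Shanghai,1.000,0.982,1.000,1.000,0.982
Jiangsu,1.019,0.976,1.018,1.001,0.995
Zhejiang,1.032,0.954,1.000,1.032,0.985
Anhui,0.951,0.973,1.005,0.947,0.926
Fujian,1.057,0.956,1.007,1.050,1.010
Jiangxi,1.016,0.961,1.012,1.003,0.976
Shandong,1.040,0.957,1.006,1.034,0.995
Henan,1.027,0.981,1.034,0.994,1.008
Hubei,1.008,0.977,1.027,0.982,0.985
Hunan,1.003,0.971,0.998,1.005,0.974
Guangdong,1.018,0.954,1.000,1.018,0.971
Guangxi,1.011,0.961,1.005,1.006,0.972
Hainan,1.071,0.928,1.007,1.063,0.993
Chongqing,0.930,0.989,0.989,0.940,0.920
Sichuan,0.977,0.998,1.000,0.977,0.975
Guizhou,0.991,0.978,1.002,0.989,0.969
Yunnan,0.944,0.988,1.003,0.941,0.933
Tibet,1.000,0.908,1.000,1.000,0.908
Shaanxi,1.001,0.954,1.000,1.000,0.955
Gansu,0.948,0.984,0.998,0.950,0.933
Qinghai,1.018,0.953,1.000,1.018,0.971
Ningxia,0.974,0.955,1.000,0.974,0.929
Xinjiang,0.939,0.973,1.000,0.939,0.914
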