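resource,year,T,T_intra,T_inter
institutions,2013,0.2250,0.2241,0.0009
institutions,2014,0.2229,0.2226,0.0003
institutions,2015,0.2266,0.2266,0.0001
institutions,2016,0.2287,0.2287,0.0000
institutions,2017,0.2341,0.2336,0.0006
beds,2013,0.1896,0.1763,0.0134
beds,2014,0.1909,0.1791,0.0117
beds,2015,0.1897,0.1779,0.0117
beds,2016,0.1922,0.1812,0.0109
beds,2017,0.1922,0.1823,0.0099
staff,2013,0.2386,0.1923,0.0462
staff,2014,0.2370,0.1961,0.0409
staff,2015,0.2313,0.1933,0.0381
staff,2016,0.2278,0.1932,0.0346
staff,2017,0.2311,0.1982,0.0329
outpatient_visits,2013,0.2887,0.2082,0.0805
outpatient_visits,2014,0.2911,0.2083,0.0828
outpatient_visits,2015,0.2891,0.2082,0.0808
outpatient_visits,2016,0.2924,0.2120,0.0804
outpatient_visits,2017,0.2912,0.2157,0.0756
discharged_patients,2013,0.2344,0.2222,0.0122
discharged_patients,2014,0.2307,0.2196,0.0111
discharged_patients,2015,0.2319,0.2217,0.0101
discharged_patients,2016,0.2542,0.2441,0.0101
discharged_patients,2017,0.2299,0.2224,0.0075
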