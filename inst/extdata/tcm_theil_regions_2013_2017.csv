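resource,region,year,t_g
institutions,eastern,2013,0.2117
institutions,eastern,2014,0.2153
institutions,eastern,2015,0.2153
institutions,eastern,2016,0.2357
institutions,eastern,2017,0.2597
institutions,middle,2013,0.0621
institutions,middle,2014,0.0588
institutions,middle,2015,0.0646
institutions,middle,2016,0.0632
institutions,middle,2017,0.0568
institutions,western,2013,0.3405
institutions,western,2014,0.3372
institutions,western,2015,0.3341
institutions,western,2016,0.3301
institutions,western,2017,0.3248
beds,eastern,2013,0.1940
beds,eastern,2014,0.1966
beds,eastern,2015,0.1972
beds,eastern,2016,0.2028
beds,eastern,2017,0.2086
beds,middle,2013,0.0859
beds,middle,2014,0.0931
beds,middle,2015,0.0964
beds,middle,2016,0.0973
beds,middle,2017,0.0969
beds,western,2013,0.2440
beds,western,2014,0.2421
beds,western,2015,0.2346
beds,western,2016,0.2372
beds,western,2017,0.2333
staff,eastern,2013,0.2062
staff,eastern,2014,0.2066
staff,eastern,2015,0.1996
staff,eastern,2016,0.2104
staff,eastern,2017,0.2157
staff,middle,2013,0.0920
staff,middle,2014,0.0985
staff,middle,2015,0.1030
staff,middle,2016,0.0996
staff,middle,2017,0.1034
staff,western,2013,0.2992
staff,western,2014,0.3012
staff,western,2015,0.2937
staff,western,2016,0.2783
staff,western,2017,0.2827
outpatient_visits,eastern,2013,0.1972
outpatient_visits,eastern,2014,0.1969
outpatient_visits,eastern,2015,0.1967
outpatient_visits,eastern,2016,0.2016
outpatient_visits,eastern,2017,0.2074
outpatient_visits,middle,2013,0.0814
outpatient_visits,middle,2014,0.0865
outpatient_visits,middle,2015,0.0913
outpatient_visits,middle,2016,0.0981
outpatient_visits,middle,2017,0.1007
outpatient_visits,western,2013,0.3320
outpatient_visits,western,2014,0.3319
outpatient_visits,western,2015,0.3251
outpatient_visits,western,2016,0.3321
outpatient_visits,western,2017,0.3216
discharged_patients,eastern,2013,0.2391
discharged_patients,eastern,2014,0.2400
discharged_patients,eastern,2015,0.2410
discharged_patients,eastern,2016,0.3192
discharged_patients,eastern,2017,0.2459
discharged_patients,middle,2013,0.1362
discharged_patients,middle,2014,0.1384
discharged_patients,middle,2015,0.1421
discharged_patients,middle,2016,0.1374
discharged_patients,middle,2017,0.1399
discharged_patients,western,2013,0.2870
discharged_patients,western,2014,0.2748
discharged_patients,western,2015,0.2759
discharged_patients,western,2016,0.2699
discharged_patients,western,2017,0.2721
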