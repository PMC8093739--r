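manta_id,sex,maturity,tag_id,deploy_date,last_detection,n_detections,tracking_days,detection_days,ri_percent,status
CG-MA-0035,F,sub-adult,890,20/11/2019,13/03/2020,1159,115,92,80,ACTIVE
CG-MA-0046,F,adult,892,25/11/2019,10/03/2020,846,107,61,57,ACTIVE
CG-MA-0070,F,adult,891,01/12/2019,17/03/2020,1059,108,46,43,ACTIVE
CG-MA-0088,M,juvenile,897,28/11/2019,15/03/2020,907,109,43,40,ACTIVE
CG-MA-0094,F,sub-adult,894,30/11/2019,13/03/2020,1116,105,67,64,ACTIVE
CG-MA-0112,M,juvenile,893,01/12/2019,13/03/2020,1129,104,49,47,ACTIVE
CG-MA-0117,F,sub-adult,887,20/11/2019,13/03/2020,718,115,50,44,ACTIVE
CG-MA-0118,M,juvenile,900,19/11/2019,11/03/2020,678,114,41,36,ACTIVE
CG-MA-0119,F,juvenile,901,19/11/2019,13/03/2020,801,116,54,47,ACTIVE
CG-MA-0120,F,adult,902,19/11/2019,21/11/2019,15,3,2,76,UNKNOWN
CG-MA-0121,M,juvenile,903,19/11/2019,13/03/2020,1770,116,84,73,ACTIVE
CG-MA-0124,M,adult,885,20/11/2019,12/03/2020,559,114,44,39,ACTIVE
CG-MA-0125,M,juvenile,895,20/11/2019,14/03/2020,1272,116,60,52,ACTIVE
CG-MA-0139,F,adult,899,25/11/2019,15/03/2020,763,112,73,66,ACTIVE
CG-MA-0140,M,juvenile,898,30/11/2019,13/03/2020,711,105,25,24,ACTIVE
CG-MA-0141,F,adult,889,28/11/2019,20/01/2020,411,54,31,58,UNKNOWN
CG-MA-0142,F,sub-adult,884,02/12/2019,15/03/2020,1216,105,59,56,ACTIVE
CG-MA-0151,M,adult,896,01/12/2019,12/03/2020,794,103,62,60,ACTIVE
CG-MA-0161,M,adult,888,02/12/2019,27/12/2019,41,26,7,27,UNKNOWN
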