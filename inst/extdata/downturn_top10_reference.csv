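country,deaths_0,lower_0,upper_0,deaths_5,additional_5,lower_5,upper_5,deaths_10,additional_10,lower_10,upper_10,deaths_15,additional_15,lower_15,upper_15
India,2929298,986082,8701895,2972361,43063,1004659,8793951,3018437,89139,1024604,8892182,3067926,138628,1046101,8997378
Nigeria,1503219,497646,4540714,1525317,22098,507077,4588238,1548962,45743,517205,4638937,1574358,71139,528124,4693221
Democratic Republic of the Congo,1388004,524706,3671682,1408409,20405,534338,3712285,1430241,42237,544670,3755652,1453691,65687,555796,3802143
China,1235908,372924,4095918,1254076,18169,380064,4138001,1273517,37609,387734,4182878,1294396,58489,396005,4230905
Pakistan,1054683,371239,2996334,1070187,15505,378185,3028413,1086777,32094,385641,3062651,1104595,49912,393676,3099329
Ethiopia,992985,369329,2669755,1007582,14598,376148,2698999,1023202,30217,383463,2730228,1039977,46993,391343,2763698
United Republic of Tanzania,523317,187417,1461240,531010,7693,190917,1476931,539241,15925,194674,1493681,548083,24766,198723,1511625
Indonesia,461840,147090,1450106,468629,6789,149891,1465156,475893,14054,152899,1481208,483696,21856,156142,1498392
Niger,461338,171118,1243775,468120,6782,174273,1257434,475377,14039,177657,1272020,483171,21833,181302,1287654
Bangladesh,435117,153268,1235269,441513,6396,156135,1248500,448358,13241,159212,1262622,455709,20592,162528,1277750
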