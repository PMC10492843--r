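wavelength_nm,eps_oxy,eps_deoxy
350,27000,17000
355,29296,18324
360,32000,20000
365,35254,22424
370,40000,26000
375,47572,31162
380,60000,40000
385,82807,58239
390,120000,90000
395,180120,146180
400,266000,223000
405,365220,273270
410,467000,304000
415,523000,325000
420,480000,380000
425,358970,464330
430,246000,529000
435,157460,496910
440,103000,413000
445,77825,305580
450,62800,216000
455,52201,157930
460,44500,117000
465,38143,87509
470,33200,68000
475,29413,57340
480,26600,50000
485,24780,43396
490,23400,38000
495,21945,33448
500,20900,30000
505,20416,27568
510,20800,26500
515,22631,26500
520,26000,26500
525,32124,27729
530,40000,30500
535,48024,34504
540,53200,39500
545,49797,44795
550,43000,50000
555,34555,53400
560,30000,53800
565,35281,51569
570,45000,48000
575,52000,43000
580,44000,37000
585,23274,30855
590,11000,25000
595,5702,19289
600,3200,14700
605,2095.8,11354
610,1510,9000
615,1169.3,7532.8
620,942,6510
625,747.72,5730.7
630,610,5150
635,520.19,4697.5
640,454.16,4329.9
645,404.99,4020.8
650,368,3750
655,339.93,3522.6
660,318.6,3337.8
665,302.54,3174
670,290.63,3013.7
675,282.01,2842.6
680,276,2650
685,273.78,2420.7
690,276.11,2178.1
695,281.87,1960.8
700,290,1794
705,300.34,1666.1
710,313.37,1554.8
715,329,1461.6
720,347.09,1387.5
725,367.49,1333.2
730,390,1300
735,416.15,1298.5
740,447.05,1327
745,481.54,1368.6
750,518,1405
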