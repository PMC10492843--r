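wavelength_nm,qy_b,qy_g,qy_r
350,0.00529006,8.01941e-07,1.74187e-12
355,0.00842782,1.73021e-06,5.08946e-12
360,0.013139,3.65297e-06,1.45519e-11
365,0.0200448,7.54721e-06,4.07157e-11
370,0.0299251,1.52588e-05,1.1148e-10
375,0.0437181,3.01888e-05,2.98691e-10
380,0.0625,5.84475e-05,7.83146e-10
385,0.0874362,0.000110733,2.00935e-09
390,0.1197,0.000205297,5.045e-09
395,0.160359,0.00037246,1.23954e-08
400,0.210224,0.000661258,2.98023e-08
405,0.26969,0.00114883,7.01187e-08
410,0.338564,0.00195313,1.6144e-07
415,0.415919,0.00324937,3.63731e-07
420,0.5,0.00529006,8.01941e-07
425,0.588198,0.00842782,1.73021e-06
430,0.677128,0.013139,3.65297e-06
435,0.762799,0.0200448,7.54721e-06
440,0.840896,0.0299251,1.52588e-05
445,0.907126,0.0437181,3.01888e-05
450,0.957603,0.0625,5.84475e-05
455,0.989228,0.0874362,0.000110733
460,1,0.1197,0.000205297
465,0.989228,0.160359,0.00037246
470,0.957603,0.210224,0.000661258
475,0.907126,0.26969,0.00114883
480,0.840896,0.338564,0.00195313
485,0.762799,0.415919,0.00324937
490,0.677128,0.5,0.00529006
495,0.588198,0.588198,0.00842782
500,0.5,0.677128,0.013139
505,0.415919,0.762799,0.0200448
510,0.338564,0.840896,0.0299251
515,0.26969,0.907126,0.0437181
520,0.210224,0.957603,0.0625
525,0.160359,0.989228,0.0874362
530,0.1197,1,0.1197
535,0.0874362,0.989228,0.160359
540,0.0625,0.957603,0.210224
545,0.0437181,0.907126,0.26969
550,0.0299251,0.840896,0.338564
555,0.0200448,0.762799,0.415919
560,0.013139,0.677128,0.5
565,0.00842782,0.588198,0.588198
570,0.00529006,0.5,0.677128
575,0.00324937,0.415919,0.762799
580,0.00195313,0.338564,0.840896
585,0.00114883,0.26969,0.907126
590,0.000661258,0.210224,0.957603
595,0.00037246,0.160359,0.989228
600,0.000205297,0.1197,1
605,0.000110733,0.0874362,0.989228
610,5.84475e-05,0.0625,0.957603
615,3.01888e-05,0.0437181,0.907126
620,1.52588e-05,0.0299251,0.840896
625,7.54721e-06,0.0200448,0.762799
630,3.65297e-06,0.013139,0.677128
635,1.73021e-06,0.00842782,0.588198
640,8.01941e-07,0.00529006,0.5
645,3.63731e-07,0.00324937,0.415919
650,1.6144e-07,0.00195313,0.338564
655,7.01187e-08,0.00114883,0.26969
660,2.98023e-08,0.000661258,0.210224
665,1.23954e-08,0.00037246,0.160359
670,5.045e-09,0.000205297,0.1197
675,2.00935e-09,0.000110733,0.0874362
680,7.83146e-10,5.84475e-05,0.0625
685,2.98691e-10,3.01888e-05,0.0437181
690,1.1148e-10,1.52588e-05,0.0299251
695,4.07157e-11,7.54721e-06,0.0200448
700,1.45519e-11,3.65297e-06,0.013139
705,5.08946e-12,1.73021e-06,0.00842782
710,1.74187e-12,8.01941e-07,0.00529006
715,5.83382e-13,3.63731e-07,0.00324937
720,1.91198e-13,1.6144e-07,0.00195313
725,6.13205e-14,7.01187e-08,0.00114883
730,1.92451e-14,2.98023e-08,0.000661258
735,5.91057e-15,1.23954e-08,0.00037246
740,1.77636e-15,5.045e-09,0.000205297
745,5.22425e-16,2.00935e-09,0.000110733
750,1.50353e-16,7.83146e-10,5.84475e-05
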