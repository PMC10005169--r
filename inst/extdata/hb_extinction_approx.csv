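wavelength_nm,eps_hbo2,eps_hb
300,32000,36000
320,30000,33000
340,28000,30000
360,33000,31000
380,58000,50000
390,125000,90000
400,266232,223296
405,350000,250000
410,466840,303956
414,524280,350000
420,480360,407560
425,350000,480000
430,246072,528600
435,150000,500000
440,102580,413280
450,62816,103292
460,44480,72000
470,33209,55000
480,26629,45000
490,23684,35000
500,20932,20862
510,24000,23000
520,31000,27000
530,43000,40000
540,53236,46592
545,55000,50000
550,43016,53412
555,36000,55000
560,33878,53788
565,36000,50000
570,44496,45072
575,50104,41000
580,48000,32000
585,35000,28000
590,17000,26630
600,3200,14677
610,1600,9500
620,942,7000
630,610,4800
640,442,4200
650,368,3750
660,320,3227
680,280,2500
700,290,1794
720,340,1600
740,446,1450
760,586,1670
780,710,1100
800,816,762
820,916,693
850,1058,691
880,1154,726
900,1198,761
950,1200,700
1000,1100,900
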