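wavelength_nm,HbO2,Hb
700,290,1794
710,320,1647
720,348,1326
730,390,1102
740,446,1116
750,518,1405
760,586,1549
770,650,1312
780,710,1075
790,762,890
800,816,762
810,864,717
820,916,694
830,974,693
840,1022,692
850,1058,691
860,1092,692
870,1122,700
880,1154,724
890,1178,739
900,1198,762
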