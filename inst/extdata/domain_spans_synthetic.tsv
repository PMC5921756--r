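protein_id	domain	start	end
CaARF1	B3	115	219
CaARF1	AUX_RESP	229	313
CaARF2	B3	115	219
CaARF2	AUX_RESP	229	313
CaARF2	III	627	652
CaARF2	IV	666	703
CaARF3	B3	115	219
CaARF3	AUX_RESP	229	313
CaARF3	III	824	849
CaARF3	IV	863	900
CaARF4	B3	115	219
CaARF4	AUX_RESP	229	313
CaARF4	III	635	660
CaARF5	B3	115	219
CaARF5	AUX_RESP	229	313
CaARF5	III	742	767
CaARF5	IV	781	818
CaARF6	B3	115	219
CaARF6	AUX_RESP	229	313
CaARF6	III	1036	1061
CaARF6	IV	1075	1112
CaARF7	B3	115	219
CaARF7	AUX_RESP	229	313
CaARF7	III	749	774
CaARF7	IV	788	825
CaARF8	B3	115	219
CaARF8	AUX_RESP	229	313
CaARF9	B3	115	219
CaARF9	AUX_RESP	229	313
CaARF10	B3	115	219
CaARF10	AUX_RESP	229	313
CaARF10	III	608	633
CaARF11	B3	115	219
CaARF11	AUX_RESP	229	313
CaARF11	III	833	858
CaARF11	IV	872	909
CaARF12	B3	115	219
CaARF12	AUX_RESP	229	313
CaARF12	III	769	794
CaARF12	IV	808	845
CaARF13	B3	115	219
CaARF13	AUX_RESP	229	313
CaARF13	III	1036	1061
CaARF13	IV	1075	1112
CaARF14	B3	115	219
CaARF14	AUX_RESP	229	313
CaARF14	III	783	808
CaARF14	IV	822	859
CaARF15	B3	115	219
CaARF15	AUX_RESP	229	313
CaARF15	III	834	859
CaARF15	IV	873	910
CaARF16	B3	115	219
CaARF16	AUX_RESP	229	313
CaARF16	III	641	666
CaARF16	IV	680	717
CaARF17	B3	115	219
CaARF17	AUX_RESP	229	313
CaARF17	III	723	748
CaARF17	IV	762	799
CaARF18	B3	115	219
CaARF18	AUX_RESP	229	313
CaARF18	III	622	647
CaARF19	B3	115	219
CaARF19	AUX_RESP	229	313
CaARF19	III	607	632
CaARF19	IV	646	683
CaARF20	B3	115	219
CaARF20	AUX_RESP	229	313
CaARF20	III	1041	1066
CaARF20	IV	1080	1117
CaARF21	B3	115	219
CaARF21	AUX_RESP	229	313
CaARF22	B3	115	219
CaARF22	AUX_RESP	229	313
CaARF22	III	595	620
CaARF22	IV	634	671
CaARF23	B3	115	219
CaARF23	AUX_RESP	229	313
CaARF24	B3	115	219
CaARF24	AUX_RESP	229	313
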