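# Published per-target dose-response summary of an 11-patient recurrent
# head-and-neck SCC cohort treated with BNCT (protocol I): minimum weighted
# tumor dose, gEUD of the EQD2-converted DVH (a = -13), EUD-based TCP
# (TCD50 = 46.8 Gy, gamma50 = 2.0) and RECIST response. The underlying
# patient DVHs are not public; these printed summaries are the exactly
# checkable fixture for the gEUD -> TCP stage.
patient_id,target_label,dbnct_min_gyw,geud_gy,tcp_percent,response
1,GTV1,6.0,21.5,0.2,PD
1,GTV2,15.3,47.2,51.6,PD
2,GTV1,6.5,21.1,0.2,SD
3,GTV1,10.0,42.3,30.8,PR
4,GTV1,12.3,41.0,25.9,PR
5,GTV1,9.2,31.9,4.4,SD
6,GTV1,19.5,68.6,95.5,CR
7,GTV1,7.0,22.4,0.3,PD
7,GTV2,22.3,63.6,92.0,PD
8,GTV1,25.3,80.7,98.7,CR
8,GTV2,19.0,56.5,81.8,CR
9,GTV1,18.5,49.8,62.3,CR
10,GTV1,9.4,44.7,40.9,PR
11,GTV1,7.9,35.7,10.3,PD
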