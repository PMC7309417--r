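mirna	av_chi2
miR-1	44.2375
miR-3	55.005
miR-8	11.87
miR-9a	94.48
miR-9b	106.515
miR-9c	67.48
miR-10	5.825
miR-12	22.215
miR-31	1.7233
miR-34	61.6733
miR-79	75.665
miR-92a	95.605
miR-92b	28.3
miR-124	82.57
miR-133	48.02
miR-137	42.74
miR-184	27.405
miR-193	47.53
miR-219	2.155
miR-263b	5.565
miR-274	22.64
miR-276b	41.435
miR-277	24.585
miR-278	77.63
miR-279	13.5
miR-287	2.255
miR-310	102.4833
miR-312	32.885
miR-313	50.71
miR-315	24.59
miR-316	2.695
miR-318	26.385
miR-375	39.25
miR-932	25.87
miR-958	25.42
miR-968	35.07
miR-977	4.7065
miR-978	70.46
miR-980	31.04
miR-989	44.38
miR-992	7.805
miR-995	7.05
miR-999	2.775
miR-1015	3.855
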