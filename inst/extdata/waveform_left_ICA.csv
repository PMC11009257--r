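time_s,flow_m3s
0,3.96247081859118e-06
0.02,4.1939503566549e-06
0.04,4.4899433814287e-06
0.06,4.83934064387598e-06
0.08,5.21351339370626e-06
0.1,5.56710713795005e-06
0.12,5.84579159634396e-06
0.14,6e-06
0.16,6e-06
0.18,5.84579159634396e-06
0.2,5.56710713795005e-06
0.22,5.21351339370626e-06
0.24,4.83934064387598e-06
0.26,4.4899433814287e-06
0.28,4.1939503566549e-06
0.3,3.96247081859118e-06
0.32,3.79317653415186e-06
0.34,3.67612327739752e-06
0.36,3.59885914066123e-06
0.38,3.54972324264528e-06
0.4,3.51935392683084e-06
0.42,3.50095854186262e-06
0.44,3.48995191641134e-06
0.46,3.48339859413079e-06
0.48,3.47949024092604e-06
0.5,3.47714243129165e-06
0.52,3.47571601950858e-06
0.54,3.47483784109874e-06
0.56,3.47429075829522e-06
0.58,3.47394840167059e-06
0.6,3.47373729371449e-06
0.62,3.47361524010391e-06
0.64,3.47355927074826e-06
0.66,3.47355927074826e-06
0.68,3.47361524010391e-06
0.7,3.47373729371449e-06
0.72,3.47394840167059e-06
0.74,3.47429075829522e-06
0.76,3.47483784109874e-06
0.78,3.47571601950858e-06
0.8,3.47714243129165e-06
0.82,3.47949024092604e-06
0.84,3.48339859413079e-06
0.86,3.48995191641134e-06
0.88,3.50095854186262e-06
0.9,3.51935392683084e-06
0.92,3.54972324264528e-06
0.94,3.59885914066123e-06
0.96,3.67612327739751e-06
0.98,3.79317653415186e-06
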