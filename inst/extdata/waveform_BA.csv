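time_s,flow_m3s
0,1.98123540929559e-06
0.02,2.09697517832745e-06
0.04,2.24497169071435e-06
0.06,2.41967032193799e-06
0.08,2.60675669685313e-06
0.1,2.78355356897503e-06
0.12,2.92289579817198e-06
0.14,3e-06
0.16,3e-06
0.18,2.92289579817198e-06
0.2,2.78355356897503e-06
0.22,2.60675669685313e-06
0.24,2.41967032193799e-06
0.26,2.24497169071435e-06
0.28,2.09697517832745e-06
0.3,1.98123540929559e-06
0.32,1.89658826707593e-06
0.34,1.83806163869876e-06
0.36,1.79942957033061e-06
0.38,1.77486162132264e-06
0.4,1.75967696341542e-06
0.42,1.75047927093131e-06
0.44,1.74497595820567e-06
0.46,1.74169929706539e-06
0.48,1.73974512046302e-06
0.5,1.73857121564583e-06
0.52,1.73785800975429e-06
0.54,1.73741892054937e-06
0.56,1.73714537914761e-06
0.58,1.7369742008353e-06
0.6,1.73686864685725e-06
0.62,1.73680762005196e-06
0.64,1.73677963537413e-06
0.66,1.73677963537413e-06
0.68,1.73680762005196e-06
0.7,1.73686864685725e-06
0.72,1.7369742008353e-06
0.74,1.73714537914761e-06
0.76,1.73741892054937e-06
0.78,1.73785800975429e-06
0.8,1.73857121564583e-06
0.82,1.73974512046302e-06
0.84,1.74169929706539e-06
0.86,1.74497595820567e-06
0.88,1.75047927093131e-06
0.9,1.75967696341542e-06
0.92,1.77486162132264e-06
0.94,1.79942957033061e-06
0.96,1.83806163869876e-06
0.98,1.89658826707593e-06
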