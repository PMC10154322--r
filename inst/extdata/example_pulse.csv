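t_s,q_ml_s
0,2.5
0.02,2.5000002832816
0.04,2.50002612097378
0.06,2.50036039072483
0.08,2.50226610020554
0.1,2.50920564719784
0.12,2.52822008545656
0.14,2.57091326626051
0.16,2.65344784516317
0.18,2.79512471605888
0.2,3.01545311818739
0.22,3.33004347681129
0.24,3.74605601487174
0.26,4.25820061671948
0.28,4.84632181997797
0.3,5.4753850908433
0.32,6.09823912895578
0.34,6.66095536747324
0.36,7.10996985025299
0.38,7.39981106144798
0.4,7.5
0.42,7.39981106144798
0.44,7.10996985025299
0.46,6.66095536747324
0.48,6.09823912895578
0.5,5.4753850908433
0.52,4.84632181997797
0.54,4.25820061671948
0.56,3.74605601487174
0.58,3.33004347681129
0.6,3.01545311818739
0.62,2.79512471605888
0.64,2.65344784516317
0.66,2.57091326626051
0.68,2.52822008545656
0.7,2.50920564719784
0.72,2.50226610020554
0.74,2.50036039072483
0.76,2.50002612097378
0.78,2.5000002832816
0.8,2.5
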