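"wavelength_nm","absorbance"
250,0.14216
255,0.12992
260,0.11874
265,0.10852
270,0.09918
275,0.09064
280,0.08284
285,0.07571
290,0.0692
295,0.06324
300,0.0578
305,0.05282
310,0.04828
315,0.04412
320,0.04032
325,0.03685
330,0.03368
335,0.03078
340,0.02813
345,0.02571
350,0.0235
355,0.02148
360,0.01963
365,0.01794
370,0.01639
375,0.01498
380,0.01369
385,0.01252
390,0.01144
395,0.01045
400,0.00955
405,0.00873
410,0.00798
415,0.00729
420,0.00667
425,0.00609
430,0.00557
435,0.00509
440,0.00465
445,0.00425
450,0.00388
455,0.00355
460,0.00324
465,0.00297
470,0.00271
475,0.00248
480,0.00226
485,0.00207
490,0.00189
495,0.00173
500,0.00158
505,0.00144
510,0.00132
515,0.00121
520,0.0011
525,0.00101
530,0.00092
535,0.00084
540,0.00077
545,7e-04
550,0.00064
555,0.00059
560,0.00054
565,0.00049
570,0.00045
575,0.00041
580,0.00037
585,0.00034
590,0.00031
595,0.00029
600,0.00026
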