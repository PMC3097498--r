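concentration_ug_ml,peak_area
0.5,341732.5
1,642338
2,1243549
3,1844760
4,2445971
5,3047182
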