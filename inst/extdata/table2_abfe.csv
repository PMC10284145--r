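system_id,dG_exp,dG_ZA1,dG_ZA1_sem,dG_ZA2,dG_ZA2_sem
3U5L,-8.16,-11.36,0.28,-6.85,0.28
4LZR,-6.40,-6.52,0.53,-2.50,0.21
4QB3,-7.55,-7.55,0.37,-4.94,0.64
4XY9,-7.03,-4.88,0.48,-2.87,0.95
5DW2,-8.00,-7.69,0.69,-8.10,0.32
5IGK,-9.73,-11.79,0.37,-4.84,0.40
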