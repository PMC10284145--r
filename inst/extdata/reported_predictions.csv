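system_id,condition,dH,sem,source
3U5L,ZA2,-6.52,0.64,computed
4QB3,QM-refined,-5.13,0.72,computed
5IGK,combined,-11.29,3.07,computed
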