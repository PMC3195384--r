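total=78
1,3,5,18,20,22,24,29,30,39,48,52,53,57,62,63,66,70,73,74,77,78
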