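1.2966672161
1.2611470807
1.1951466200
1.1401307615
1.2618303290
1.1500935658
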