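((cell_1:22,cell_2:22):6,(cell_3:10,cell_4:10):18):4;
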