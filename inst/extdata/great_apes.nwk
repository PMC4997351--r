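(((Human:5,Chimpanzee:5):3,Gorilla:8):3,Orangutan:11);
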