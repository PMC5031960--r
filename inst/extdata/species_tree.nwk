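(the:0.35,(tom:0.25,(cof:0.15,(rha:0.08,(cra:0.05,rsa:0.05):0.03):0.07):0.10):0.10);
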