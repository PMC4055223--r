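term,estimate,se
intercept,14.56,2.14
sex,-0.98,0.51
age,-0.84,0.13
paq,1.01,0.39
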