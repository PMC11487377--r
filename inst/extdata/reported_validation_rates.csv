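metric,value
sensitivity,0.9259
specificity,0.9242
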