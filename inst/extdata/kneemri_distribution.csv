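category,count
not_injured,690
partially_injured,172
completely_ruptured,55
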