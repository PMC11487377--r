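split,n_exams,n_acl_tear
training,1130,208
validation,120,54
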