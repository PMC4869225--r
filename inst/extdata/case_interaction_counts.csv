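source_type,individual,organizational,media,policy
individual,672,125,267,48
organizational,132,68,18,17
media,8,2,9,1
policy,8,5,0,2
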