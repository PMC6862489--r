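marker,chromosome,pos_mb
J521,chr2,7.6
RM3390,chr2,7.7
J527,chr2,8.2
J529,chr2,8.6
J536,chr2,9.1
RM6375,chr2,9.6
RM1358,chr2,10.2
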