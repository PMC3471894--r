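id_a	id_b	rpair_id
serine	glycine	RP00001
citrate	succinate	RP00002
succinate	fumarate	RP00003
fumarate	malate	RP00004
ornithine	putrescine	RP00005
glucose	citrate	RP00006
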