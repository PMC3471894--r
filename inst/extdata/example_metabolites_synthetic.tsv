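id	name	fingerprint
alanine	alanine	1000011111010010001000001000001000000000000000010001100000000110010100100000001000001100000000010011010010000100000000110000000000100110000100000000010001100000000000010100000001010010000001100000010001110010100110001000100001010011000000000010000000000001
serine	serine	1000011001010000001000001000001000000000000000010001100000000110010100000010001000001100000100010011010110000100000000111100000000000110000110000000010001100000000000010100100001010010000001100000000001110010000110001000100001010011000000000010000000000001
glycine	glycine	1000011111010000001000001000001000000000000000010001000000000110010101000000001000001100000000011011010110010100000000111100001000100110000100000000010001100000000000010100000001010000000001100000000001110010000100001000100001010011000000000001000000000001
glutamine	glutamine	1000011111010000001000001000011000000000000000010001100000000110000001000000011000001100000000010011010110000100000000111100000000101110000100000000010001100000000000010100000001010010000001100000000000110010000010101000100001010011000000000010000000000001
citrate	citrate	0011001000001000000001001011001010010000010000100111110010110010010010000000010000100000000000001000000010010000001010000001000000000100001110101000100011000000000000000001000000010001000000000000001010010001000010000001000101000100000000000110101001011000
succinate	succinate	0011001000001000000001001010001010010001000000100111110001110010000010000000010000100000000000001100001010010001001010000001000000000100001110101000100011000001000000000001100000010000000000000000001010010001000010000001000000000100000000000111001001011000
fumarate	fumarate	0011001000001000000001001010001010010001000000100110110011110010000010000011010000100000000000001100000010010001001010000001000000000100001110101000100011000000000000001001100000010000000000000000001010010001000010000001000000000100000000000110101001001000
malate	malate	0011001010000000000001001010001010010000000000100111110010110010000010000000011000100000000000001100000010010001001010001001000000000100001110101000100010000000000000000001100000010000000000000000001010010001000010000001000101000100000000100110101001010000
glucose	glucose	0000100000101001010101000100000001000100000000010001000001000100000000000001010001001001000001100000100000010000010000001111001000000000001001000000011001001001000000001100001010001000000101100011001000100000001000100010110000000110010000000000000100011010
ornithine	ornithine	0000001000100000001001110000000000010110000110000001000110000100101010001000001010000010001100100000001001010010000000100010000101000000000100000101010010000100100010001000000010001001000100000000000100010000101001010000000000000000101000001000010011010100
putrescine	putrescine	0000000000100000001001110000000000010110001110000001000100000100101010001000001010000010001100000000001001010010000000100010000101000000000100000101010010010100100010001010000000001001000000000000100100000010101000010100000001000000101000001000010011010100
xanthine	xanthine	0000000001110000000011000010010101101101000000101111100100000000110111010101000100000000000000010100000010010000000101000000000001100000110100110100000000000000010000100001000000000000000010000100000010000010010000000110011000010000000000000100010100000010
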