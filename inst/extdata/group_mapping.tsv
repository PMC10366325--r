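state1	state2	group
UP	DOWN	G1
DOWN	UP	G2
UP	UP	G3
UP	STABLE	G4
DOWN	DOWN	G5
DOWN	STABLE	G6
STABLE	UP	G7
STABLE	DOWN	G8
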