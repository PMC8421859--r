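loop	start	end	sequence
1	20	31	DKDGDGTITTKE
2	56	67	DADGNGTIDFPE
3	93	104	DKDGNGYISAAE
4	129	140	DIDGDGQVNYEE
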