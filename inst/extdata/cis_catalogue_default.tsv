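name	pattern	scope	count_mode
internal_SD	AGGAGG	internal	overlap
polyU_tract	TTTTT	anywhere	run
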