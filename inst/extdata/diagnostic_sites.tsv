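position	state_rumiko	state_cresphontes
10	T	C
19	T	C
79	C	T
82	C	T
106	T	C
223	T	C
235	T	C
238	T	A
286	C	T
287	C	T
319	A	C
340	C	T
364	C	T
433	A	G
616	C	T
628	A	G
640	T	C
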