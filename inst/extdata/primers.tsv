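name	orientation	sequence	tail5
LepF	forward	TGTAAAACGACGGCCAGTATTCAACCAATCATAAAGATATTGG	18
LepR	reverse	CAGGAAACAGCTATGACCTAAACTTCTGGATGTCCAAAAAATCA	18
swtl-COIF	forward	TTATTCAACAAATCATAAAGATATCGGA	0
swtl-mCOIR	reverse	GTTCCKGCYCCATTTTCTAC	0
sCOIF	forward	ATTCAACCAATCATAAAGATATTGG	0
smCOIR	reverse	CCTGTTCCAGCTCCATTTTC	0
swtl-mCOIF	forward	GACTTTTACCCCCTTCTCTAACTC	0
swtl-COIR	reverse	AAAATATAAACTTCAGGATGTCCAAA	0
paeon-COIF	forward	TCAACAAATCATAAAGATATCGGAAC	0
swtl-bCOIR	reverse	AATCAATTTCCAAATCCTCCAA	0
swtl-bCOIF	forward	CCGGCTCATTAATTGGAGATG	0
swtl-mCOIR-4seg	reverse	CTGTTCCKCTYCCATTTTCTAC	0
swtl-mCOIF2	forward	TTTTGACTTTTACCCCCTTCTCTAA	0
swtl-eCOIR	reverse	CCTACGGCTCAAACAAATAAAGG	0
swtl-eCOIF	forward	TTCCTCAATTCTTGGRGCAATTA	0
swtl-COIR2	reverse	AAAATATAAACTTCAGGATGTCCAAAAA	0
swtl-ID1F	forward	TGAGCAAGAATACTAGGAACTTCTCTTA	0
swtl-ID1R	reverse	AATAAAAGCATGAGCTGTAACAATAGTA	0
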