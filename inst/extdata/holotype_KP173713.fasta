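>KP173713|Heraclides rumiko|USA: Texas: Duval Co.|full
AACATTATATTTTATTTTTGGAATTTGAGCAAGAATACTAGGAACTTCTCTTAGTTTACTAATTCGTACT
GAATTAGGCACCCCCGGCTCATTAATTGGAGATGATCAAATTTATAATACTATTGTTACAGCTCATGCTT
TTATTATAATTTTTTTTATAGTTATACCTATTATAATTGGAGGATTTGGAAATTGATTAATTCCATTAAT
ATTAGGAGCCCCTGATATAGCTTTTCCTCGTATAAATAATATAAGATTTTGACTTTTACCCCCTTCTCTA
ACTCTCCTAATTTCAAGAATAATTGTAGAAAATGGGGCAGGAACTGGATGAACTGTTTACCCTCCTCTTT
CCTCTAATATTGCCCATGGAAGAAGATCAGTAGATTTAGTTATCTTTTCTTTACATTTAGCTGGTATTTC
CTCAATTCTTGGAGCAATTAATTTTATTACTACAATTATTAATATACGAATTAATAGAATATCTTTTGAT
CAAATACCTTTATTTGTTTGAGCCGTAGGAATTACAGCTTTATTATTACTTTTATCTTTACCTGTTTTAG
CAGGAGCTATTACTATACTTTTAACTGATCGAAATTTAAATACTTCATTTTTTGACCCTGCTGGAGGAGG
AGATCCAATTTTATACCAACATTTATTT
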