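name	sequence
V1	ATTGTGGTCCGAACCCTGGT
V2	CCGGGGAAGGAGCTGGCCTG
V3	GTACGGCACGACCCTCCCAT
V4	TACAAATACTAACACCACCC
V5	GCTCGCCGGAAAGCATAAGT
V6	ACGGTTGAGGATTCTCGGTC
V7	CCCGAAGATCTGAGCATTCT
V8	ACATACCAGGCTTTAATACC
V9	TTAAAGTCTGCGGCCCCTAC
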