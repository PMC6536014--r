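# Top 10 nodes by betweenness centrality (published CRC screening study)
SRC
EGFR
PCNA
IL8
CTNNB1
TIMP1
HSPB1
CDH1
SPTAN1
HSPD1
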