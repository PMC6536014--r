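# Top 10% of main-component nodes by degree (published CRC screening study)
SRC
EGFR
CTNNB1
CDH1
IL8
PCNA
TIMP1
HSPD1
PTPRC
SERPINA1
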