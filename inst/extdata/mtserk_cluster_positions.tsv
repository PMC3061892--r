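gene	start_kbp	end_kbp
MtSERK2	1603.3	1609.6
MtSERK3	1610.0	1616.1
MtSERK4	1615.7	1621.4
MtSERK5	1622.7	1628.9
MtSERK6	1629.2	1636.2
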