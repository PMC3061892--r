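name	sequence	orientation
Forward1	CARTTYCARCANGARGTNGAAATGAT	forward
Forward2	CARTTYCARCANGARGTNGAGATGAT	forward
Reverse1	CCRTANCCRAANACRTCNGTYTTTTC	reverse
Reverse2	CCRTANCCRAANACRTCNGTYTTCTC	reverse
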