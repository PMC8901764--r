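gene	observed_knockdown	lipid_effect
ZNF436	decrease	none
WARS2	none	none
TBX15	decrease	decrease
INVS	none	none
STX17	decrease	none
PCK1	decrease	decrease
EBPL	none	none
NID2	decrease	decrease
GGA3	decrease	decrease
MRPS7	none	none
NUP85	decrease	none
GRB2	decrease	decrease
PEMT	none	none
ZNF263	unknown	unknown
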