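AKT1
API5
DNAJC14
EIF2B4
ELA
ERCC3
GLUD1
HDAC3
HMGB1
IFNAR1
MLH1
OAZ1
PUM1
RIPK1
SF3A1
STAT3
TBC1D10B
TLK2
TMUB2
UBB
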