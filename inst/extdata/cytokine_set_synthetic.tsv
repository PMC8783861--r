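gene
IL2
IL11
TNFRSF4
FASLG
PRLR
IL6
IL10
IL1A
IL1B
IL12A
IL12B
IL15
IL18
IL7
IL4
IL5
IL13
IL17A
IL21R
IL2RA
IL2RB
IL2RG
IL6R
IL10RA
IL10RB
CXCL8
CXCL9
CXCL10
CXCL11
CXCL12
CXCL13
CCL2
CCL3
CCL4
CCL5
CCL13
CCL19
CCL21
CCR2
CCR5
CCR7
CXCR3
CXCR4
TNF
TNFRSF9
TNFRSF18
TNFSF10
TGFB1
TGFB2
IFNG
IFNGR1
CSF1
CSF1R
CSF2
KITLG
LTA
CYTSIM001
CYTSIM002
CYTSIM003
CYTSIM004
CYTSIM005
CYTSIM006
CYTSIM007
CYTSIM008
CYTSIM009
CYTSIM010
CYTSIM011
CYTSIM012
CYTSIM013
CYTSIM014
CYTSIM015
CYTSIM016
CYTSIM017
CYTSIM018
CYTSIM019
CYTSIM020
CYTSIM021
CYTSIM022
CYTSIM023
CYTSIM024
CYTSIM025
CYTSIM026
CYTSIM027
CYTSIM028
CYTSIM029
CYTSIM030
CYTSIM031
CYTSIM032
CYTSIM033
CYTSIM034
CYTSIM035
CYTSIM036
CYTSIM037
CYTSIM038
CYTSIM039
CYTSIM040
CYTSIM041
CYTSIM042
CYTSIM043
CYTSIM044
CYTSIM045
CYTSIM046
CYTSIM047
CYTSIM048
CYTSIM049
CYTSIM050
CYTSIM051
CYTSIM052
CYTSIM053
CYTSIM054
CYTSIM055
CYTSIM056
CYTSIM057
CYTSIM058
CYTSIM059
CYTSIM060
CYTSIM061
CYTSIM062
CYTSIM063
CYTSIM064
CYTSIM065
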