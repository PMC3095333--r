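name	pattern
CBOXLIKE	TGACGT
ABRELATERD1	ACGTG
CACGTGMOTIF	CACGTG
GT1CONSENSUS	GRWAAW
CAATBOX1	CCAAT
TATABOX5	TTATTT
WBOXNTERF3	TGACY
MYBCORE	CNGTTR
GATABOX	GATA
DOFCOREZM	AAAG
ARR1AT	NGATT
EBOXBNNAPA	CANNTG
IBOXCORE	GATAA
POLLEN1LELAT52	AGAAA
SEF4MOTIFGM7S	RTTTTTTR
CACTFTPPCA1	YACT
GTGANTG10	GTGA
TAAAGSTKST1	TAAAG
MYCCONSENSUSAT	CANNTG
CCAATBOX1	CCAAT
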