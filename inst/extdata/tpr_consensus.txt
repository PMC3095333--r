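# Idealized 34-residue tetratricopeptide repeat (TPR) consensus, version 1.
# Position model: BLOSUM62 log-odds scores against this consensus, one
# column per repeat position. See ?tpr_profile.
AEAWYNLGNAYYKQGDYDEAIEYYQKALELDPNN
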