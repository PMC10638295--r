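# Curated genes whose recurrent cancer mutations are established
# gain-of-function drivers; excluded when screening for novel
# change-of-function candidates. Edit freely: one symbol per line.
IDH1
IDH2
EZH2
PIK3CA
BRAF
KRAS
NRAS
HRAS
GNAS
AKT1
JAK2
KIT
EGFR
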