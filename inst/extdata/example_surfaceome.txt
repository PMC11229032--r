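# Example surfaceome gene list (one symbol per line).
# For a real screen, supply the full plasma-membrane set (GO:0005886).
CEACAM6
DPEP1
S100P
MLANA
CD19
MS4A1
EGFR
ERBB2
MSLN
GPC3
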