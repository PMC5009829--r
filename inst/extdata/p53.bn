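# Major switch of the p53 pathway: ATM, p53, Wip1, Mdm2 (node order fixed).
# High expression = 1, low expression = 0.
ATM  = !Wip1
p53  = ATM & !Mdm2
Wip1 = p53
Mdm2 = !ATM & (p53 | Wip1)
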