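source,a_cm2,b_cm2,ratio_printed_pct
brand,124.6,33.6,26.00
klein_horsmann,204.5,80.9,39.50
lube,99.7,45.7,45.70
pierrynowski,127.2,52.4,41.20
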