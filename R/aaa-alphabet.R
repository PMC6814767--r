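# Canonical 20-letter amino-acid alphabet, in the conventional scale order.
AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
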