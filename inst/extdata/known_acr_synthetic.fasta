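>synthAcr1 synthetic stand-in for an experimentally validated anti-CRISPR (not a real protein)
MKTAYVDQLGERIKAWLNDPEGFKQLVESMTRHHALNPDQWIGGKLSEYVNRATELMKQS
GDLVKAHEWFRNTLPESMQAYLDKVNGIMREHPELAKRFVDETLNSWKQG
>synthAcr2 synthetic stand-in for an experimentally validated anti-CRISPR (not a real protein)
MSELIKRFADNPQWVTGHLKEYSDRAMELVNQCGDWIKTHEFWRNSLPDAMQTYLEKVNG
LMRQHPEIAKRFIDESLNAWKQGMKTAYVDQLGDRIKAWLNDPEGFKQLV
>synthAcr3 synthetic stand-in for an experimentally validated anti-CRISPR (not a real protein)
MTDLVKQHEWFRNTLPESMQAYLDKVNGIMREHPELAKRFVDETLNSWKQGSELIKRFAD
NPQWVTGHLKEYSDRAMELVNQCGDWIKTHEAWRNSLPDAMKTYLEKVNG
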