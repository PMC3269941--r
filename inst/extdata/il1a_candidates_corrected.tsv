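TaxID	GeneID	Name	Column Header	Score
9606	3552	IL1A	Synonyms	1.0000
9606	3552	IL1ALPHA	Synonyms	1.0000
9606	3552	IL-1A	Synonyms	1.0000
9606	3552	IL1A	AuthorizedSymbol	1.0000
9606	3552	IL1-ALPHA	Synonyms	1.0000
9606	3552	IL1A	Symbol	1.0000
9606	3552	IL-1 alpha	OtherDesignations	1.0000
9606	3554	IL-1R-alpha	Synonyms	1.0000
9606	26525	IL1F5 (Canonical product IL-1F5a)	OtherDesignations	0.7459
9606	27177	IL1F8 (Canonical product IL-1F8a)	OtherDesignations	0.7459
9606	84639	IL-1F10 (canonical form IL-1F10a)	OtherDesignations	0.7459
9606	3552	IL1	Synonyms	0.6417
9606	3553	IL1	Synonyms	0.6417
9606	3553	IL-1	Synonyms	0.6417
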