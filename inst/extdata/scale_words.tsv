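word	exponent	kind
hundred	2	finite
hundreds	2	finite
thousand	3	finite
thousands	3	finite
hundred thousand	5	finite
million	6	finite
millions	6	finite
billion	9	finite
billions	9	finite
trillion	12	finite
trillions	12	finite
quadrillion	15	finite
quadrillions	15	finite
quintillion	18	finite
sextillion	21	finite
septillion	24	finite
octillion	27	finite
nonillion	30	finite
decillion	33	finite
undecillion	36	finite
googol	100	finite
googolplex	NA	nonrepresentable
infinity	NA	nonfinite
minus infinity	NA	nonfinite
negative infinity	NA	nonfinite
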