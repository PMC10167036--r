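name	role	formula
geranylhydroquinone	GHQ core	C16H22O2
(Z)-3''-OH-GHQ	compound 1	C16H22O3
(E)-3''-OH-GHQ	compound 2	C16H22O3
(E)-3''-oxo-GHQ	compound 3	C16H20O3
NADP+	oxidized cofactor	C21H28N7O17P3
NADPH	reduced cofactor	C21H30N7O17P3
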