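Marker	PIC	MAF	Heterozygosity	Missing value
C1	0.50	0.45	0.05	0.02
C2	0.24	0.14	0.03	0.06
C3	0.50	0.45	0.06	0.01
C4	0.46	0.35	0.06	0.02
C5	0.49	0.44	0.05	0.01
C6	0.22	0.12	0.02	0.01
C7	0.46	0.35	0.10	0.01
C8	0.45	0.34	0.06	0.00
C9	0.32	0.20	0.01	0.06
C10	0.29	0.18	0.06	0.01
C11	0.49	0.42	0.06	0.02
C12	0.33	0.21	0.01	0.01
C13	0.39	0.27	0.04	0.02
C14	0.48	0.39	0.08	0.03
C15	0.37	0.24	0.06	0.01
C16	0.47	0.38	0.05	0.02
C17	0.50	0.47	0.01	0.01
C18	0.50	0.46	0.00	0.00
C19	0.28	0.17	0.07	0.02
C20	0.49	0.42	0.09	0.02
C21	0.12	0.07	0.01	0.06
C22	0.14	0.07	0.00	0.00
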