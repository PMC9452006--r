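# Synthetic GEM-style ICD-9 -> ICD-10 crosswalk (illustrative only).
# Columns: icd9 icd10 flags (flags ignored); repeated icd9 rows list
# candidates in preference order.
4280 I509 00000
4281 I5020 10000
4281 I5022 10000
41401 I2510 00000
496 J449 00000
5849 N179 00000
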