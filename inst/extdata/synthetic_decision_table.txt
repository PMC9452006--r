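# Synthetic ACME-style decision table (illustrative only; not the real
# ACME table). 2-token lines: cause effect. 3-token lines: range rule
# (cause_low cause_high effect).
I251 I469
I251 I38
I38 I429
I429 I469
I10 I15 I519
J189 J969
J440 J449 J969
R909 J189
E109 N179
N179 I469
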