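cohort	homodel	heterodel	intact	excluded_homodel	excluded_heterodel	excluded_intact
discovery	5	6	110	0	0	0
transcriptomic	0	1	74	0	0	0
public_a	1	1	107	0	0	0
public_b	23	11	531	0	0	0
epic450_reference	57	16	494	28	0	43
validation_450k	10	5	125	0	0	0
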