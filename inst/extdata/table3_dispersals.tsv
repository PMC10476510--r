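# Published counts of inferred dispersal events between Papuan georegions,
# by time bin (Ma) and source/destination region. Region codes: mainland
# terranes E (EPCT), A (Accreted Terranes), F (Fold Belt), V (Vogelkop
# Peninsula), C (Australian Craton); island groups L (Louisiade Archipelago),
# W (Woodlark), D (D'Entrecasteaux), B (New Britain).
# The published 10-3 Ma block prints a mainland marginal of 11 while its
# legible cells sum to 10; the F->V count in that bin is reconstructed so
# that the block and grand totals (29 mainland-to-mainland, 42 to islands,
# 71 overall) are internally consistent.
bin	from	to	count
20-15	E	A	3
20-15	E	F	3
15-10	E	A	4
15-10	E	F	1
15-10	E	L	9
15-10	E	W	2
15-10	A	F	3
15-10	F	A	1
15-10	F	V	1
10-3	E	A	1
10-3	E	L	8
10-3	E	W	4
10-3	E	D	11
10-3	A	V	1
10-3	A	C	1
10-3	F	E	2
10-3	F	A	3
10-3	F	C	1
10-3	F	V	1
10-3	V	C	1
3-0	E	A	2
3-0	E	L	1
3-0	E	D	5
3-0	E	B	1
3-0	A	B	1
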