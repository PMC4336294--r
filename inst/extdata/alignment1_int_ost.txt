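# Overlap reading with an implied child of 1936.ELL.
taxonomy 1936 Guenther_1936
(ELL ELLcarlud ELL_IC)

taxonomy 1954 Voss_1954
(PER Pcarlud Prectir Psubcin)

articulation alignment1_int_ost
[1954.Pcarlud equals 1936.ELLcarlud]
[1954.Prectir disjoint 1936.ELLcarlud]
[1954.Psubcin disjoint 1936.ELLcarlud]
[1954.PER overlaps 1936.ELL]
[1954.PER disjoint 1936.ELL_IC]

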