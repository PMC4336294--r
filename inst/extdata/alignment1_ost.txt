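# Alignment of Guenther (1936) and Voss (1954), ostensive reading.
# Modes: check | worlds | mir | containment | merge | repair | question
taxonomy 1936 Guenther_1936
(ELL ELLcarlud)

taxonomy 1954 Voss_1954
(PER Pcarlud Prectir Psubcin)

articulation alignment1_ost
[1954.Pcarlud equals 1936.ELLcarlud]
[1954.Prectir disjoint 1936.ELLcarlud]
[1954.Psubcin disjoint 1936.ELLcarlud]
[1954.PER {includes is_included_in overlaps} 1936.ELL]

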