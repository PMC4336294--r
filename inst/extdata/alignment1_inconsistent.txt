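# Genus-level overlap asserted without an implied child: inconsistent;
# the repair mode lists the minimal corrections.
taxonomy 1936 1936
(ELL ELLcarlud)

taxonomy 1954 1954
(PER Pcarlud Prectir Psubcin)

articulation alignment1_inconsistent
[1954.Pcarlud equals 1936.ELLcarlud]
[1954.Prectir disjoint 1936.ELLcarlud]
[1954.Psubcin disjoint 1936.ELLcarlud]
[1954.PER overlaps 1936.ELL]

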