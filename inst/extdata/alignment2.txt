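# Alignment of Voss (1954) and Wibmer & OBrien (1986): fully congruent.
taxonomy 1954 Voss_1954
(PER Pcarlud Prectir Psubcin)

taxonomy 1986 WibmerOBrien_1986
(PER Pcarlud Prectir Psubcin)

articulation alignment2
[1986.Pcarlud equals 1954.Pcarlud]
[1986.Prectir equals 1954.Prectir]
[1986.Psubcin equals 1954.Psubcin]
[1986.PER equals 1954.PER]

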