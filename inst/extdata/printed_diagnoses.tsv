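species	genus	marker	prefix	start	end	barcode	allowance	sep	fragment	provenance
Pseudoentrophospora kesseensis	Pseudoentrophospora	ITS	ITS2	127	146	gaaccgcaaattacgcatta	1	comma	ITS2 positions 127–146 gaaccgcaaattacgcatta, one mismatch allowed	species Diagnosis paragraph, Fig. F3
Pseudoentrophospora kesseensis	Pseudoentrophospora	LSU		486	515	gaacaggtcaacatcaattcttattgccat	1	comma	positions 486–515 gaacaggtcaacatcaattcttattgccat, one mismatch allowed	species Diagnosis paragraph, Fig. F3
Hoforsa rebekkae	Hoforsa	ITS	ITS2	108	127	ggratcycccgaggtgtgaaac	1	semicolon	ITS2 positions 108–127 ggratcycccgaggtgtgaaac; one mismatch allowed	species Diagnosis paragraph, Fig. F4
Hoforsa rebekkae	Hoforsa	LSU		546	565	ctcctggtgctctcacccgt	0	semicolon	positions 546–565 ctcctggtgctctcacccgt; no mismatch allowed	species Diagnosis paragraph, Fig. F4
Kahvena rebeccae	Kahvena	ITS	ITS2	200	218	cattcgcaggaatagccag	1	semicolon	ITS2 positions 200–218 cattcgcaggaatagccag; one mismatch allowed	species Diagnosis paragraph, Fig. F5
Kahvena rebeccae	Kahvena	LSU		653	683	acgcaagctccagatcgaatctccgggctaa	1	semicolon	positions 653–683 acgcaagctccagatcgaatctccgggctaa; one mismatch allowed	species Diagnosis paragraph, Fig. F5
Kelottijaervia shannonae	Kelottijaervia	ITS		212	239	taatgtgagtgcaggaaatattatgact	1	semicolon	positions 212–239 taatgtgagtgcaggaaatattatgact; one mismatch allowed	species Diagnosis paragraph, Fig. F6
Kelottijaervia shannonae	Kelottijaervia	LSU		600	619	ctttggggtggcggtcgctg	1	semicolon	positions 600–619 ctttggggtggcggtcgctg; one mismatch allowed	species Diagnosis paragraph, Fig. F6
Kungsaengena shadiae	Kungsaengena	ITS	ITS2	25	44	tgggaacccatttcgtcgga	1	semicolon	ITS2 positions 25–44 tgggaacccatttcgtcgga; one mismatch allowed	species Diagnosis paragraph, Fig. F7
Kungsaengena shadiae	Kungsaengena	LSU		665	694	cgttggggctgggacgcccgtcgctcgcac	1	semicolon	positions 665–694 cgttggggctgggacgcccgtcgctcgcac; one mismatch allowed	species Diagnosis paragraph, Fig. F7
Langduoa dianae	Langduoa	ITS		87	106	actgagccttgcagcaacaatctccccttt	0	semicolon	positions 87–106 actgagccttgcagcaacaatctccccttt; no mismatch allowed	species Diagnosis paragraph, Fig. F8
Langduoa dianae	Langduoa	LSU		617	636	ccctctcggggggctgggga	0	semicolon	positions 617–636 ccctctcggggggctgggga; no mismatch allowed	species Diagnosis paragraph, Fig. F8
Lehetua indrekii	Lehetua	ITS		219	248	ttataatcttacgaagtactgaggtgatta	1	semicolon	positions 219–248 ttataatcttacgaagtactgaggtgatta; one mismatch allowed	species Diagnosis paragraph, Fig. F9
Lehetua indrekii	Lehetua	LSU		515	546	aactaaaggratgtggctcctcggagtgttta	1	semicolon	positions 515–546 aactaaaggratgtggctcctcggagtgttta; one mismatch allowed	species Diagnosis paragraph, Fig. F9
Lokruma stenii	Lokruma	ITS		159	178	taacttaattttttcccgag	1	semicolon	positions 159–178 taacttaattttttcccgag; one mismatch allowed	species Diagnosis paragraph, Fig. F10
Moostea stephanieae	Moostea	ITS		68	97	gcagatgatcgtgagggagttctcttcttc	1	semicolon	positions 68–97 gcagatgatcgtgagggagttctcttcttc; one mismatch allowed	species Diagnosis paragraph, Fig. F11
Moostea stephanieae	Moostea	LSU		436	455	tgggcttctgctccggcgta	1	semicolon	positions 436–455 tgggcttctgctccggcgta; one mismatch allowed	species Diagnosis paragraph, Fig. F11
Nikkaluokta mahdiehiae	Nikkaluokta	ITS		97	116	cctgggcaaatttttttttc	1	semicolon	positions 97–116 cctgggcaaatttttttttc; one mismatch allowed	species Diagnosis paragraph, Fig. F12
Nikkaluokta mahdiehiae	Nikkaluokta	LSU		687	717	cttggatataagaagtggaatctacacaaat	1	semicolon	positions 687–717 cttggatataagaagtggaatctacacaaat; one mismatch allowed	species Diagnosis paragraph, Fig. F12
Parnigua craigii	Parnigua	ITS		51	80	actgagccttgcagcaacaatctccccttt	0	semicolon	positions 51–80 actgagccttgcagcaacaatctccccttt; no mismatch allowed	species Diagnosis paragraph, Fig. F13
Parnigua craigii	Parnigua	LSU		444	463	ggcgggaaatcagcccccct	0	semicolon	positions 444–463 ggcgggaaatcagcccccct; no mismatch allowed	species Diagnosis paragraph, Fig. F13
Riederberga sylviae	Riederberga	ITS	ITS2	186	215	gctttggacggcatgcgaatctgcatcaca	1	semicolon	ITS2 positions 186–215 gctttggacggcatgcgaatctgcatcaca; one mismatch allowed	species Diagnosis paragraph, Fig. F14
Riederberga sylviae	Riederberga	LSU		656	685	tcaccaatcgacgtcaatcggcatgcgtct	1	semicolon	positions 656–685 tcaccaatcgacgtcaatcggcatgcgtct; one mismatch allowed	species Diagnosis paragraph, Fig. F14
Ruua coralieae	Ruua	ITS		217	243	gaaaaaaaaagaaaggaaagaaaaggt	1	semicolon	positions 217–243 gaaaaaaaaagaaaggaaagaaaaggt; one mismatch allowed	species Diagnosis paragraph, Fig. F15
Ruua coralieae	Ruua	LSU		470	489	tagtgcacttgctttcgcac	0	semicolon	positions 470–489 tagtgcacttgctttcgcac; no mismatch allowed	species Diagnosis paragraph, Fig. F15
Tammsaarea vivikae	Tammsaarea	ITS		228	257	ggaccgagaaggcgcaatagttgaacaatt	1	semicolon	positions 228–257 ggaccgagaaggcgcaatagttgaacaatt; one mismatch allowed	species Diagnosis paragraph, Fig. F16
Tammsaarea vivikae	Tammsaarea	LSU		585	604	ataactatcggacaaagttt	1	semicolon	positions 585–604 ataactatcggacaaagttt; one mismatch allowed	species Diagnosis paragraph, Fig. F16
Unemaeea nathalieae	Unemaeea	ITS	5.8S	122	151	gtcagtgtttgccacggagtatgccggctt	0	semicolon	5.8S positions 122–151 gtcagtgtttgccacggagtatgccggctt; no mismatch allowed	species Diagnosis paragraph, Fig. F17
Unemaeea nathalieae	Unemaeea	LSU		694	723	gggcttgtcatggcagagggacacgtcgta	0	semicolon	positions 694–723 gggcttgtcatggcagagggacacgtcgta; no mismatch allowed	species Diagnosis paragraph, Fig. F17
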