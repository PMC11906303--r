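# total_reads_N2Oexc: 75200000
# total_reads_N2Olim: 64500000
# units: bin_size_mbp Mbp; mapped_reads reads; spectra_pct percent of metaproteome
# note: per-MAG read mapping and metaproteome spectra fractions of the two enrichment metagenomes
regime	mag_id	bin_size_mbp	mapped_reads	spectra_pct	taxonomy
N2Oexc	AZO_exc	2.7	62591220	75.8	Azonexus
N2Oexc	Bin.2_exc	3.2	1470411	5.4	Phaeovulum
N2Oexc	Bin.24_exc	3.3	1160565	5.1	Pseudorhodobacter
N2Oexc	Bin.15_exc	3.5	4181484	3.7	Bdellovibrio
N2Oexc	Bin.3_exc	3.1	328268	0.8	Aquamicrobium
N2Oexc	Bin.12_exc	3.1	245691	0.3	Flavobacterium filum
N2Oexc	Bin.18_exc	2.7	547907	0.3	Moheibacter
N2Oexc	Bin.16_exc	2.5	213672	0.2	Kaistella
N2Oexc	Bin.17_exc	2.9	241612	0.1	Ferruginibacter
N2Oexc	Bin.9_exc	2.5	131267	0.0	Ferruginibacter
N2Oexc	unbinned	26.4	4099244	8.4	-
N2Olim	AZO_lim	2.7	43300280	50.8	Azonexus
N2Olim	THA_lim	4.2	1247092	13.5	Thauera phenylacetica
N2Olim	Bin.14_lim	2.0	78531	2.1	Weeksellaceae
N2Olim	Bin.21_lim	2.6	520671	1.8	Ferruginibacter
N2Olim	Bin.6_lim	2.5	243575	0.7	Seleniivibrio woodruffii
N2Olim	Bin.24_lim	1.3	486035	0.5	Patescibacteria
N2Olim	Bin.20._lim	3.1	141837	0.4	Azovibrio restrictus
N2Olim	Bin.26_lim	2.4	134723	0.2	Pseudoflavonifractor
N2Olim	Bin.11_lim	3.9	214463	0.1	Bacteroidales
N2Olim	Bin.2_lim	1.7	233247	0.1	Anaerovoracaceae
N2Olim	Bin.8_lim	2.6	101235	0.1	Niabella
N2Olim	Bin.10_lim	2.9	262567	0.1	Bacteroidales
N2Olim	Bin.1_lim	1.1	43318	0.1	Paracholeplasma
N2Olim	Bin.27_lim	3.4	142977	0.0	Fusibacter_C
N2Olim	Bin.23_lim	2.4	461252	0.0	Bacteroidales
N2Olim	Bin.22_lim	1.3	53843	0.0	Erysipelotrichaceae
N2Olim	Bin.18_lim	2.4	140114	0.0	Paludibacteraceae
N2Olim	unbinned	14.9	16727548	29.5	-
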