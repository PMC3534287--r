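# Reactive-centre P2-P1' codes and inhibitory-class calls for the 14
# full-length rice serpins (Oryza sativa cv. Nipponbare).  Rows with
# table3 = TRUE are the 11 putatively inhibitory serpins of the printed
# reactive-centre comparison table; the other three (PLP, PTY, PGY) carry
# the published class assessments (PLP strongly non-inhibitory; PTY and
# PGY less confidently non-inhibitory, recorded here as uncertain).
# See rice_locus_discrepancies.tsv for conflicting locus assignments.
locus_id	code	class_label	table3	name
Os01g16200	QKG	inhibitory	TRUE	OsSRP-QKG
Os01g56010	LGC	inhibitory	TRUE	OsSRP-LGC
Os03g41419	LRS	inhibitory	TRUE	OsSRP-LRS
Os03g41438	FRS	inhibitory	TRUE	OsSRP-FRS
Os04g45110	PTY	uncertain	FALSE	OsSRP-PTY
Os04g45120	PGY	uncertain	FALSE	OsSRP-PGY
Os11g11500	PLP	non_inhibitory	FALSE	OsSRP-PLP
Os11g11760	PSG	inhibitory	TRUE	OsSRP-PSG
Os11g12410	GAA	inhibitory	TRUE	OsSRP-GAA
Os11g12420	GRA	inhibitory	TRUE	OsSRP-GRA
Os11g12460	FAS	inhibitory	TRUE	OsSRP-FAS
Os11g12520	GMS	inhibitory	TRUE	OsSRP-GMS
Os11g13530	LLS	inhibitory	TRUE	OsSRP-LLS
Os11g13540	FLC	inhibitory	TRUE	OsSRP-FLC
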