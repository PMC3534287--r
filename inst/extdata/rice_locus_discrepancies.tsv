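# Locus-assignment conflicts in the published source annotations for the
# rice serpins.  Shipped as printed; deliberately not reconciled.  The
# packaged locus table follows the reactive-centre comparison table plus
# the supplementary serpin list.
item	assignment_a	assignment_b	note
OsSRP-PTY	Os04g45110	Os11g12410	Revised-gene-models section lists PTY at Os04g45110 in its opening paragraph but edits 'OsSRP-PTY (Os11g12410)' later; the comparison table assigns Os11g12410 the code GAA.
OsSRP-PGY	Os04g45120	Os11g12420	Revised-gene-models section lists PGY at Os04g45120 in its opening paragraph but edits 'OsSRP-PGY (Os11g12420)' later; the comparison table assigns Os11g12420 the code GRA.
OsSRP-LRS	Os03g41419	Os04g41419	One expression-results passage prints 'Os04g41419' for OsSRP-LRS; all other sections use Os03g41419.
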