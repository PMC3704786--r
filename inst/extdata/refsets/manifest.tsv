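id	set	component	provenance
synLuxI_1	luxI	AHL synthase	synthetic reconstruction (constructed in-package, not a database download)
synLuxI_2	luxI	AHL synthase	synthetic reconstruction (constructed in-package, not a database download)
synLuxI_3	luxI	AHL synthase	synthetic reconstruction (constructed in-package, not a database download)
synLuxR_1	luxR	AHL receptor	synthetic reconstruction (constructed in-package, not a database download)
synLuxR_2	luxR	AHL receptor	synthetic reconstruction (constructed in-package, not a database download)
synLuxR_3	luxR	AHL receptor	synthetic reconstruction (constructed in-package, not a database download)
synNqrA	nqr	NqrA	synthetic reconstruction (constructed in-package, not a database download)
synNqrB	nqr	NqrB	synthetic reconstruction (constructed in-package, not a database download)
synNqrC	nqr	NqrC	synthetic reconstruction (constructed in-package, not a database download)
synNqrD	nqr	NqrD	synthetic reconstruction (constructed in-package, not a database download)
synNqrE	nqr	NqrE	synthetic reconstruction (constructed in-package, not a database download)
synNqrF	nqr	NqrF	synthetic reconstruction (constructed in-package, not a database download)
synEctA_1	ectA	EctA	synthetic reconstruction (constructed in-package, not a database download)
synEctA_2	ectA	EctA	synthetic reconstruction (constructed in-package, not a database download)
synEctB_1	ectB	EctB	synthetic reconstruction (constructed in-package, not a database download)
synEctB_2	ectB	EctB	synthetic reconstruction (constructed in-package, not a database download)
synEctC_1	ectC	EctC	synthetic reconstruction (constructed in-package, not a database download)
synEctC_2	ectC	EctC	synthetic reconstruction (constructed in-package, not a database download)
synArdo_1	ardo	ARDO alpha (Rieske 17)	synthetic reconstruction (constructed in-package, not a database download)
synArdo_2	ardo	ARDO alpha (Rieske 17)	synthetic reconstruction (constructed in-package, not a database download)
synArdo_3	ardo	ARDO alpha (Rieske 17)	synthetic reconstruction (constructed in-package, not a database download)
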