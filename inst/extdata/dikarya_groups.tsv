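group	match_type	match
I	composition	GAF
II	composition	none
III	label	group-III
IV	composition	PAS
V	composition	PAS-PAS
VI	composition	HAMP
VII	composition	GAF-GAF
VIII	label	phytochrome-VIII-Fph
IX	composition	PAS-GAF
X	composition	GAF-PAS
XI	label	dual-HHK
XII	composition	HAMP-GAF
XIII	composition	PAS-PAS-GAF
XIV	composition	HAMP-PAS
XV	composition	GAF-GAF-GAF
XVI	composition	HAMP-HAMP
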