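outer	inner	dG
cg	cg	-3.30
cg	gc	-2.40
cg	gu	-1.40
cg	ug	-2.10
cg	au	-2.10
cg	ua	-2.10
gc	cg	-3.40
gc	gc	-3.30
gc	gu	-1.50
gc	ug	-2.50
gc	au	-2.40
gc	ua	-2.20
gu	cg	-2.50
gu	gc	-2.10
gu	gu	-0.50
gu	ug	1.30
gu	au	-1.30
gu	ua	-1.40
ug	cg	-1.50
ug	gc	-1.40
ug	gu	0.30
ug	ug	-0.50
ug	au	-1.00
ug	ua	-0.60
au	cg	-2.20
au	gc	-2.10
au	gu	-0.60
au	ug	-1.40
au	au	-0.90
au	ua	-1.10
ua	cg	-2.40
ua	gc	-2.10
ua	gu	-1.00
ua	ug	-1.30
ua	au	-1.30
ua	ua	-0.90
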