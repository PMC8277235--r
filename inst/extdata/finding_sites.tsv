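term	code	label
nose	45206002	Nasal structure
gum	113279002	Gingival structure
hand	33712006	Skin structure of hand
scalp	41695006	Structure of scalp
abdomen	818983003	Structure of abdomen
neck	45048000	Neck structure
chest	51185008	Thoracic structure
leg	30021000	Structure of lower leg
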