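phenotype_code	site_code	coordinated_code	coordinated_label
131148009	45206002	249366005	epistaxis
131148009	113279002	86276007	gingival bleeding
22253000	818983003	21522001	abdominal pain
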