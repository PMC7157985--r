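record_id	description	gold_code	group_id
r001	Coronary atherosclerotic heart disease	I25.101	p1
r002	essential  Hypertension grade III	I10 06	p1
r003	type 2 diabetes mellitus	E11.901	p1
r004	acute gastroenteritis	A09.901	p2
r005	community-acquired pneumonia	J18.901	p2
r006	lumbar disc herniation	M51.202	p2
r007	pneumonia with type 2 diabetes	E11.901	p3
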