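code	pattern	canonical_label	note
I25.101	coronary (atherosclerotic )?heart disease	coronary atherosclerotic heart disease	synthetic example
I10 06	(essential )?hypertension( grade (I|II|III))?	essential hypertension grade III	synthetic example
E11.901	type 2 diabetes( mellitus)?	type 2 diabetes mellitus	synthetic example
A09.901	^(acute )?gastroenteritis$	acute gastroenteritis	synthetic example
J18.901	pneumonia	pneumonia	synthetic example
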