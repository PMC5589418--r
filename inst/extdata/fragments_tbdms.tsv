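metabolite	fragment_name	formula	n_backbone_carbons	n_measured_shifts
glutamine	m431	C19H43N2O3Si3	5	7
glutamate	m432	C19H42NO4Si3	5	7
alpha-ketoglutarate	m346	C14H28NO5Si2	5	7
fumarate	m287	C12H23O4Si2	4	6
malate	m419	C18H39O5Si3	4	6
aspartate	m418	C18H40NO4Si3	4	6
citrate	m459	C20H39O6Si3	6	8
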