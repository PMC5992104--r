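term	semantic_class	functional_block
cell death	cell death	cell death
apoptotic process	cell death - apoptosis	cell death
programmed cell death	cell death	cell death
regulation of cellular response to stress	stress	response to stimulus
cellular response to stress	stress	response to stimulus
cell projection organization	cell projections	intracellular organization
plasma membrane bounded cell projection organization	cell projections	intracellular organization
cellular component organization	intracellular organization	intracellular organization
cellular component organization or biogenesis	intracellular organization	intracellular organization
intracellular transport	transport - intracellular	transport
establishment of localization in cell	localization	protein metabolism
neuron projection development	development - neuronal - axon	development
cell development	development	development
neurogenesis	development - neuronal	development
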