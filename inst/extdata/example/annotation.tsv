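g001	acyl-transferase homolog
g002	cinnamate 4-hydroxylase-like oxidase
g003	3-ketoacyl-CoA synthase
g004	aldehyde dehydrogenase family protein
g005	hypothetical protein
g006	uncharacterized protein
g007	protein of unknown function
g008	ribosomal protein L3
g009	actin-related protein
g010	heat shock protein 70
g011	ubiquitin family protein
g012	
g013	
g014	
g015	
g016	
g017	
g018	
g019	
g020	
g021	
g022	
g023	
g024	
g025	
g026	
g027	
g028	
g029	
g030	
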