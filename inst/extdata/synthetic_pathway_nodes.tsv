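id	kind
f00001	gene
f00002	gene
f00003	gene
f00004	gene
f00005	gene
f00010	gene
f00020	gene
f00030	gene
M_nad	metabolite
M_glutamate	metabolite
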