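f00001	reaction	f00002
f00002	reaction	f00003
f00003	transport	M_nad
M_nad	reaction	f00004
f00004	reaction	f00005
f00005	indirect	f00010
f00010	reaction	M_glutamate
M_glutamate	transport	f00020
f00020	reaction	f00030
f00030	indirect	f00001
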