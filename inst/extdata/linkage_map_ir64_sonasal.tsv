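chromosome	n_markers	map_length_cM
Os_Chr01	398	334.8
Os_Chr02	298	280.7
Os_Chr03	377	342.2
Os_Chr04	237	256.4
Os_Chr05	224	225.6
Os_Chr06	230	234.7
Os_Chr07	244	231.8
Os_Chr08	193	195.3
Os_Chr09	157	141.0
Os_Chr10	130	146.4
Os_Chr11	162	184.4
Os_Chr12	135	156.9
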