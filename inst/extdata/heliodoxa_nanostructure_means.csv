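taxon,patch,trait,mean,ci_lo,ci_hi
branickii,crown,air,87,64,111
branickii,crown,cortex,133,106,153
branickii,crown,ker,26,15,36
branickii,crown,n_layers,13,12,14
branickii,crown,mel,37,28,46
branickii,crown,pt_top,85,67,107
branickii,gorget,air,126,93,151
branickii,gorget,cortex,173,157,192
branickii,gorget,ker,39,25,66
branickii,gorget,n_layers,9,9,10
branickii,gorget,mel,52,41,65
branickii,gorget,pt_top,168,141,190
branickii,tail,air,90,67,112
branickii,tail,cortex,64,45,87
branickii,tail,ker,25,6,37
branickii,tail,n_layers,5,4,6
branickii,tail,mel,40,32,48
branickii,tail,pt_top,165,132,207
hybrid,crown,air,91,78,115
hybrid,crown,cortex,108,95,126
hybrid,crown,ker,32,23,45
hybrid,crown,n_layers,16,12,21
hybrid,crown,mel,44,34,53
hybrid,crown,pt_top,91,72,113
hybrid,gorget,air,149,116,179
hybrid,gorget,cortex,139,111,164
hybrid,gorget,ker,39,19,65
hybrid,gorget,n_layers,12,10,14
hybrid,gorget,mel,49,39,61
hybrid,gorget,pt_top,198,167,224
hybrid,tail,air,89,65,110
hybrid,tail,cortex,52,30,78
hybrid,tail,ker,17,12,22
hybrid,tail,n_layers,3,3,4
hybrid,tail,mel,44,36,58
hybrid,tail,pt_top,165,147,197
gularis,crown,air,101,76,126
gularis,crown,cortex,146,124,168
gularis,crown,ker,32,24,44
gularis,crown,n_layers,11,7,14
gularis,crown,mel,39,32,46
gularis,crown,pt_top,123,100,152
gularis,gorget,air,102,65,133
gularis,gorget,cortex,159,129,199
gularis,gorget,ker,33,20,47
gularis,gorget,n_layers,8,6,10
gularis,gorget,mel,52,40,60
gularis,gorget,pt_top,174,128,206
gularis,tail,air,79,50,102
gularis,tail,cortex,52,31,77
gularis,tail,ker,33,19,54
gularis,tail,n_layers,3,2,3
gularis,tail,mel,56,43,68
gularis,tail,pt_top,211,186,229
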