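label,age_kyr,sigma_kyr,role,unit
LCC3,248,31,direct,0
LCC1,143,24,direct,1
LCC2,133,19,direct,1
CC10,164,24,direct,1
CC11,149,22,direct,1
CC12,140,23,direct,1
CCF1,104,27,minimum,2
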