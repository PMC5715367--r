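stress,value,year
salt,66,
arsenic,64,
phosphate,345.54,
freezing,50,2011
freezing,74,2013
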