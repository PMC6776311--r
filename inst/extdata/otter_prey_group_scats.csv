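river,year,n_scats
Mopan,2016,40
Pasion,2010,52
Pasion,2015,40
San Pedro,2009,36
San Pedro,2015,117
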