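stage,n,pct_printed
total_entries,790206,NA
missing_metadata,51,0.01
nonnumeric,1073,0.14
core_excluded,11486,1.45
final_inrange,42504,5.38
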