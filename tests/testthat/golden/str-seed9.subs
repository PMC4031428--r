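taxon_0001 = taxon_0001,taxon_0001_dup1
taxon_0002 = taxon_0002,taxon_0002_subs2
taxon_0004 = taxon_0004,taxon_0004_subs1
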