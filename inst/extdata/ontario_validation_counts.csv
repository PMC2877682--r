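surname_derived,South Asian,Chinese,General Population
South Asian,654,4,129
Chinese,9,899,139
General Population,737,226,67062
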