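# Published whole-plastome alignment statistics (one IR copy and all
# indel columns removed before phylogenetic analysis).
metric	value
aligned_nucleotides	127010
invariant_nucleotides	123302
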