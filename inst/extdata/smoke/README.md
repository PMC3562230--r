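# Synthetic smoke fixture

All files in this directory are SYNTHETIC, generated by
`cebpameth::end_to_end_fixture(simulation_config(seed = 2013, n_cases = 30), ...)`.
The reference FASTA is the deterministic synthetic promoter (TSS at index 1501),
not a genomic sequence.
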