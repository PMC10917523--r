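>synthetic_signal_peptide hydrophobic N-terminal stretch (synthetic test sequence)
MLFKAVVLTAALAASNVAWAGGIVLDGSHHH
>synthetic_mixed control peptide with alternating character (synthetic test sequence)
MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ
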