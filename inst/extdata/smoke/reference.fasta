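>synthetic_promoter tss_offset=1501
ACTTAGATCATGATTGACTTAGATCATGATTGACTTAGATCATGATTGACTTAGATCATGATTGACTTAGATCATGACGG
ACTTAGATCACGATTGACTTAGACGATGATTGACTTCGATCATGATTGACGTAGATCATGATCGACTTAGATCATCGTTG
ACTTAGATCGTGATTGACTTACGTCATGATTGACCGAGATCATGATTCGCTTAGATCATGCGTGACTTAGATCACGATTG
ACTTAGACGATGATTGACTTCGATCATGATTGACGTAGATCATGATCGACTTAGATCATCGTTGACTTAGATCGTGATTG
ACTTACGTCATGATTGACCGAGATCATGATTCGCTTAGATCATGCGTGACTTAGATCCGCGTTGACTTAGACGATGATTG
ACCGAGATCATGATCGACTTAGATCACGATTGACTTAGCGCATGATTGACGTAGATCATGACGGACTTAGATCCGGATTG
ACTTACGTCATGATTGCGTTAGATCATGCGTGACTTAGATCGTGATTGACTTCGATCATGATTCGCTTAGATCATCGTTG
ACTTAGACGATGATTGACTCGGATCATGATCGACTTAGATCACGATTGACTTAGATCATGATTGACTTAGATCATGATTG
ACTTAGATCATGATTGACTTAGATCATGATTGACTTAGATCATGATTGACTTAGATCATGATTGACTTAGATCATGATTG
ACTTAGATCATGATTGACTTAGATCATGATTGACTTAGATCATGATTGACTTAGATCATGATTGACTTAGATCATGATTG
ACTTAGATCATGATTGACTTAGATCATGATTGACTTAGATCATGATTGACTTAGATCATGATTGACTTAGATCATGATTG
ACTTAGATCATGATTGACTTAGATCATGATTGACTTAGATCATGATTGACTTAGATCATGATTGACTTAGATCATGATTG
ACTTAGATCATGATTGACTTAGATCATGATTGACTTAGATCATGATTGACTTAGATCATGATTGACTTAGATCATGATTG
ACTTAGATCATGATTGACTTAGATCATGATTGACTTAGATCATGATTGACTTAGATCATGATTGACTTAGATCATGATTG
ACTTAGATCATGATTGACTTAGATCATGATTGACTTAGATCATGATTGACTTAGATCATGATTGACTTAGATCATGATTG
ACTTAGATCATGATTGACTTAGATCATGATTGACTTAGATCATGATTGACTTAGATCATGATTGACTTAGATCATGATTG
ACTTAGATCATGATTGACTTAGATCATGATTGACTTAGATCATGATTGACTTAGATCATGATTGACTTAGATCATGATTC
GCTTAGACGATGATTCGCTTAGACGATGATTGACTTAGATCATGATTGACTTAGATCATGATTGACTTAGATCATGATTG
ACTTAGATCATGATTGACTTAGATCATGATTGACTTAGATCATGATTGACTTAGATCATGATTGACTTAGATCATGATTG
ACTTAGATCATGATTGACTTAGATCATGATTGACTTAGATCATGATTGACTTAGCGCATGATCGACTTAGCGCATGATCG
ACTTAGATCATGATTGACTTAGATCATGATTGACTTAGATCATGATTGAC
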