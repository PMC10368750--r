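# Versioned alignment-threshold profiles used across the pipeline.
# All comparisons are inclusive (a hit exactly at a floor is retained).
version: 1
profiles:
  rbh:                 # reciprocal best hits between the two morphotype sets
    min_pident: 70
    min_qcov: 70
  est:                 # in-silico EST validation
    max_evalue: 1.0e-5
    min_pident: 95
    min_qcov: 95
  own_lnc:             # own-species lncRNA database, top 3 hits per query
    max_evalue: 1.0e-5
    min_pident: 70
    min_qcov: 70
    top_n: 3
  zebrafish_lnc:       # zebrafish lncRNA database
    max_evalue: 1.0e-5
    min_pident: 50
    min_qcov: 50
  human_lnc:           # human lncRNA database (coverage relaxed to 25)
    max_evalue: 1.0e-5
    min_pident: 50
    min_qcov: 25
  fish_screen:         # two-round fish conservation screen
    max_evalue: 1.0e-3
    min_qcov: 60
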