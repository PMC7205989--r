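Synthetic example reference annotation table (RAT).

synthetic_gh_rat.tsv      4-column envelope dialect: md5, domain, env_start, env_end
synthetic_gh_lengths.tsv  companion length table: domain, length (amino acids)

The protein MD5 identifiers and envelope coordinates are synthetic.
GH70's canonical length (805 AA) is the published reference length for
the glycoside hydrolase normalization; every other length here is a
synthetic stand-in chosen for the examples, not a Pfam model length.
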