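region	length_bp	candidate_sites	defining_sites	seed_site
Dup1	127000	1214	24	10766895
Dup2	170000	1774	25	11476819
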