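version = crms-default-1.0
menses_codes = H,M,L
count_of_three = 3
peak_plus_fertile = 3
peak_plus_end_of_day = 4
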