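# ATC-class parameters, finest defined prefix wins.
# min_ddd_per_day: below this dose average the period is split
# common_ddd_per_day: fallback dose for refill-length estimates
# min_period_days: fallback duration when nothing else is known
# max_refill_days: longest refill allowed in continuous use
atc_prefix,min_ddd_per_day,common_ddd_per_day,min_period_days,max_refill_days
N,0.02,1,10,200
N05A,0.02,1,10,200
N06A,0.05,1,14,200
C10AA,0.05,1,30,250
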