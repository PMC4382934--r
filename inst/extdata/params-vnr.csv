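# Package (vnr) parameters: refill-length window and the daily doses the
# window corresponds to. Finest level; overrides ATC-class values.
vnr,min_refill_days,max_refill_days,typical_refill_days,ddd_per_day_at_min,ddd_per_day_at_max,ddd_per_day_typical
012345,15,120,30,2,0.25,1
010940,49,118,98,0.66,0.27,0.33
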