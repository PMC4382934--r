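# Global modelling constants. Every key is optional; omitted keys keep the
# package defaults shown here. Global limits cannot be overridden by
# ATC-class or package parameters.
max_refill_gap_days: 300        # larger net gaps restart the dose average
max_hospital_days_in_period: 30 # longest continuous stay bridged at period end
max_ddd_per_day: 10             # cap on any applied daily dose
max_single_purchase_days: 150   # hard cap on one-purchase periods
dvar: 0.5                       # weight on the regularity multiplier 1+dvar*cv
adherence_slack: 0.2            # non-adherence allowance for typical-dose lengths
mode_min_purchases: 10          # joined count a refill mode must exceed
refill_source_min_purchases: 6  # purchases a period needs to teach refills
ddd_avg_min_purchases: 3        # purchases a segment needs for dose averages
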