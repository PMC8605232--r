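# Whole-flock descriptive items recorded alongside the 50-bird assessment:
# beak trimming (not permitted in Norway), observed antagonistic incidents,
# flock flightiness category, birds needing further care, and
# producer-reported mortality (percent or "unknown").
house_id,beak_trimmed,antagonistic_incidents,flightiness,birds_needing_care,mortality_previous,mortality_to_date
1,no,1,calm,1,2.1,unknown
2,no,0,cautious,3,3.1,2.0
3,no,2,calm,3,2.1,0.9
4,no,4,calm,8,unknown,unknown
5,no,0,calm,2,4.4,2.0
6,no,2,calm,3,3.1,1.6
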