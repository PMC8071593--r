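label,theme
Social media use,online
Influencer exposure,online
Unrealistic body ideals,emotional
Self esteem,emotional
Motivation to exercise,physical_activity
Physical activity,physical_activity
Screen time,online
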