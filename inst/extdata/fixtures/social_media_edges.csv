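source_label,target_label,polarity
Social media use,Influencer exposure,+1
Influencer exposure,Unrealistic body ideals,+1
Unrealistic body ideals,Self esteem,-1
Self esteem,Motivation to exercise,+1
Motivation to exercise,Physical activity,+1
Physical activity,Screen time,-1
Screen time,Social media use,+1
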