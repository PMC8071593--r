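source_label,target_label,polarity
Body weight,Body image pressure,+1
Body image pressure,Self esteem,-1
Self esteem,Stress,-1
Stress,Stress eating,+1
Stress eating,Unhealthy food intake,+1
Unhealthy food intake,Body weight,+1
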