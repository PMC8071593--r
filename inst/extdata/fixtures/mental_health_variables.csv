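label,theme
Body weight,body_weight
Body image pressure,emotional
Self esteem,emotional
Stress,emotional
Stress eating,food_drink
Unhealthy food intake,food_drink
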