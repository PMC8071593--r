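source_label,target_label,polarity
Food company power,Unhealthy food advertising,+1
Unhealthy food advertising,Exposure to unhealthy food,+1
Exposure to unhealthy food,Demand for unhealthy food,+1
Demand for unhealthy food,Unhealthy food consumption,+1
Unhealthy food consumption,Food company profit,+1
Food company profit,Food company power,+1
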