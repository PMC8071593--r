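label,theme
Food company power,economic_commercial
Unhealthy food advertising,economic_commercial
Exposure to unhealthy food,economic_commercial
Demand for unhealthy food,economic_commercial
Unhealthy food consumption,economic_commercial
Food company profit,economic_commercial
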