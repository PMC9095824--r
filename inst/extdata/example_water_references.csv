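region,d18O_water_min,d18O_water_max
Punjab,-8.5,-6.5
GangeticPlain,-6.0,-3.0
Coastal,-3.5,-1.5
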