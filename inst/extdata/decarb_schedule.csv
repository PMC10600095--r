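sector,step_year,multiplier
electricity,2030,0.45
electricity,2040,0.15
electricity,2050,0.05
fuels,2030,0.75
fuels,2040,0.45
fuels,2050,0.15
gas_energy,2030,0.85
gas_energy,2040,0.6
gas_energy,2050,0.35
heat,2030,0.7
heat,2040,0.4
heat,2050,0.12
minerals,2030,0.8
minerals,2040,0.55
minerals,2050,0.3
resins,2030,0.85
resins,2040,0.55
resins,2050,0.25
transport,2030,0.75
transport,2040,0.5
transport,2050,0.2
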