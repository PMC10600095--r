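category,half_life_years
carcassing,35
fencing,20
fence_poles,20
packaging_pallets,20
particleboard,25
mdf,25
recycled_mdf,25
other,20
woodfuel,0
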