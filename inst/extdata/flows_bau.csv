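scenario_id,source,target,quantity
bau,forest_gate,sawmill,55
bau,forest_gate,particleboard_mill,8
bau,forest_gate,mdf_mill,12
bau,forest_gate,woodfuel_chain,15
bau,forest_gate,fence_poles,4
bau,forest_gate,other,6
bau,sawmill,carcassing,22
bau,sawmill,fencing,8
bau,sawmill,packaging_pallets,8
bau,sawmill,particleboard_mill,7
bau,sawmill,mdf_mill,4
bau,sawmill,woodfuel_chain,5
bau,sawmill,loss_sawmill,1
bau,waste_wood_recovered,particleboard_mill,6
bau,waste_wood_recovered,woodfuel_chain,10
bau,particleboard_mill,particleboard,20
bau,particleboard_mill,loss_panel,1
bau,mdf_mill,mdf,15.5
bau,mdf_mill,loss_panel,0.5
bau,woodfuel_chain,woodfuel,30
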