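scenario_id,source,target,quantity
circular,forest_gate,sawmill,67
circular,forest_gate,particleboard_mill,6
circular,forest_gate,mdf_mill,5
circular,forest_gate,woodfuel_chain,12
circular,forest_gate,fence_poles,4
circular,forest_gate,other,6
circular,sawmill,carcassing,22
circular,sawmill,fencing,11
circular,sawmill,packaging_pallets,14
circular,sawmill,particleboard_mill,8
circular,sawmill,mdf_mill,3
circular,sawmill,woodfuel_chain,8
circular,sawmill,loss_sawmill,1
circular,waste_wood_recovered,particleboard_mill,7
circular,waste_wood_recovered,woodfuel_chain,1
circular,waste_mdf_recovered,recycled_mdf_mill,8
circular,particleboard_mill,particleboard,20
circular,particleboard_mill,loss_panel,1
circular,mdf_mill,mdf,7.5
circular,mdf_mill,loss_panel,0.5
circular,recycled_mdf_mill,recycled_mdf,7.5
circular,recycled_mdf_mill,loss_panel,0.5
circular,woodfuel_chain,woodfuel,21
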