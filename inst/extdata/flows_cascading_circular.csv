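scenario_id,source,target,quantity
cascading_circular,forest_gate,sawmill,74
cascading_circular,forest_gate,particleboard_mill,3
cascading_circular,forest_gate,mdf_mill,3
cascading_circular,forest_gate,woodfuel_chain,10
cascading_circular,forest_gate,fence_poles,4
cascading_circular,forest_gate,other,6
cascading_circular,sawmill,carcassing,31
cascading_circular,sawmill,fencing,11
cascading_circular,sawmill,packaging_pallets,13
cascading_circular,sawmill,particleboard_mill,8
cascading_circular,sawmill,mdf_mill,2
cascading_circular,sawmill,woodfuel_chain,8
cascading_circular,sawmill,loss_sawmill,1
cascading_circular,waste_wood_recovered,particleboard_mill,7
cascading_circular,waste_wood_recovered,woodfuel_chain,1
cascading_circular,waste_mdf_recovered,recycled_mdf_mill,8
cascading_circular,particleboard_mill,particleboard,17
cascading_circular,particleboard_mill,loss_panel,1
cascading_circular,mdf_mill,mdf,4.5
cascading_circular,mdf_mill,loss_panel,0.5
cascading_circular,recycled_mdf_mill,recycled_mdf,7.5
cascading_circular,recycled_mdf_mill,loss_panel,0.5
cascading_circular,woodfuel_chain,woodfuel,19
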