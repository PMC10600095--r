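scenario_id,source,target,quantity
cascading,forest_gate,sawmill,70
cascading,forest_gate,particleboard_mill,3
cascading,forest_gate,mdf_mill,4
cascading,forest_gate,woodfuel_chain,13
cascading,forest_gate,fence_poles,4
cascading,forest_gate,other,6
cascading,sawmill,carcassing,32
cascading,sawmill,fencing,10
cascading,sawmill,packaging_pallets,10
cascading,sawmill,particleboard_mill,8
cascading,sawmill,mdf_mill,2
cascading,sawmill,woodfuel_chain,7
cascading,sawmill,loss_sawmill,1
cascading,waste_wood_recovered,particleboard_mill,6
cascading,waste_wood_recovered,woodfuel_chain,10
cascading,particleboard_mill,particleboard,16
cascading,particleboard_mill,loss_panel,1
cascading,mdf_mill,mdf,5.5
cascading,mdf_mill,loss_panel,0.5
cascading,woodfuel_chain,woodfuel,30
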