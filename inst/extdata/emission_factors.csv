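process_id,scope,value_kgco2e,unit,decarb_sector
forest_gate,1,9,green tonne,fuels
forest_gate,1,5,green tonne,transport
forest_gate,2,1,green tonne,electricity
forest_gate,3,1,green tonne,resins
sawmill,1,8,green tonne,fuels
sawmill,2,18,green tonne,electricity
sawmill,3,3,green tonne,resins
particleboard_mill,1,40,green tonne,heat
particleboard_mill,2,55,green tonne,electricity
particleboard_mill,3,60,green tonne,resins
particleboard_mill,3,5,green tonne,transport
mdf_mill,1,60,green tonne,heat
mdf_mill,2,75,green tonne,electricity
mdf_mill,3,100,green tonne,resins
mdf_mill,3,5,green tonne,transport
recycled_mdf_mill,1,30,green tonne,heat
recycled_mdf_mill,2,45,green tonne,electricity
recycled_mdf_mill,3,60,green tonne,resins
recycled_mdf_mill,3,5,green tonne,transport
woodfuel_chain,1,20,green tonne,fuels
woodfuel_chain,2,20,green tonne,electricity
woodfuel_chain,3,6,green tonne,transport
import_processing_carcassing,3,46,green tonne,heat
import_processing_fencing,3,46,green tonne,heat
import_processing_packaging_pallets,3,46,green tonne,heat
import_processing_fence_poles,3,20,green tonne,heat
import_processing_particleboard,3,185,green tonne,heat
import_processing_mdf,3,264,green tonne,heat
import_processing_woodfuel,3,62,green tonne,heat
import_processing_other,3,20,green tonne,heat
import_transport_carcassing,3,30,green tonne,transport
import_transport_fencing,3,30,green tonne,transport
import_transport_packaging_pallets,3,30,green tonne,transport
import_transport_fence_poles,3,30,green tonne,transport
import_transport_particleboard,3,30,green tonne,transport
import_transport_mdf,3,30,green tonne,transport
import_transport_woodfuel,3,30,green tonne,transport
import_transport_other,3,30,green tonne,transport
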