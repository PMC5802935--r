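# Carbon flux budget of the Northern Highlands Lake District (NHLD),
# Wisconsin/Michigan: best-estimate total fluxes with ranges among the three
# major landscape compartments (forest, wetland, surface_waters) and the
# un-simplified exterior ("external"). Self-rows are storage terms
# (accumulation, sediment). Litter rows are totals; the per-shoreline
# intensities live in nhld_intensities.csv.
source,target,process,orientation,best,low,high,units
external,forest,GPP,vertical,3233,3119,3347,Gg C yr-1
external,forest,precipitation,vertical,6.2,4.1,8.3,Gg C yr-1
forest,forest,accumulation,internal,968,873,1063,Gg C yr-1
forest,external,respiration,vertical,2238,2176,2301,Gg C yr-1
forest,surface_waters,DIC_runoff,lateral,10,4,17,Gg C yr-1
forest,surface_waters,DOC_runoff,lateral,14,5,23,Gg C yr-1
forest,surface_waters,litter,lateral,2.3,1.2,3.5,Gg C yr-1
external,wetland,GPP,vertical,878,836,919,Gg C yr-1
external,wetland,precipitation,vertical,3.2,2.1,4.3,Gg C yr-1
wetland,wetland,accumulation,internal,89,27,152,Gg C yr-1
wetland,external,respiration,vertical,754,679,829,Gg C yr-1
wetland,external,CH4,vertical,13,1,25,Gg C yr-1
wetland,surface_waters,DIC_runoff,lateral,1.0,-2.2,4.2,Gg C yr-1
wetland,surface_waters,DOC_runoff,lateral,20,4,35,Gg C yr-1
wetland,surface_waters,litter,lateral,0.7,0.3,1.0,Gg C yr-1
external,surface_waters,precipitation,vertical,1.5,1.0,2.0,Gg C yr-1
surface_waters,surface_waters,accumulation,internal,-15,-40,9,Gg C yr-1
surface_waters,surface_waters,sediment,internal,17,8,26,Gg C yr-1
surface_waters,external,CO2_evasion,vertical,28,22,34,Gg C yr-1
surface_waters,external,CH4,vertical,2.2,1.1,3.3,Gg C yr-1
surface_waters,external,runoff_export,lateral,34,23,45,Gg C yr-1
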