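# NHLD local flux intensities (best estimates) and compartment geometry.
# basis: areal = g C m-2 yr-1; lineal = g C m-1 of shoreline yr-1;
#        area = m2; length = km (donor-to-surface-water interface).
# Compartment areas are not published directly; they are back-derived from
# (total flux) / (local intensity) pairs of the same budget:
#   forest         3233 Gg / 936 g m-2  = 3454059829.06 m2
#   wetland         878 Gg / 490 g m-2  = 1791836734.69 m2
#   surface_waters   17 Gg /  20 g m-2  =  850000000.00 m2 (sediment pair)
compartment,process,basis,value,units
all,precipitation,areal,1.8,g C m-2 yr-1
forest,GPP,areal,936,g C m-2 yr-1
forest,respiration,areal,648,g C m-2 yr-1
forest,DIC_runoff,areal,3.0,g C m-2 yr-1
forest,DOC_runoff,areal,4.0,g C m-2 yr-1
forest,litter,lineal,300,g C m-1 yr-1
wetland,GPP,areal,490,g C m-2 yr-1
wetland,respiration,areal,421,g C m-2 yr-1
wetland,CH4,areal,10,g C m-2 yr-1
wetland,DIC_runoff,areal,0.6,g C m-2 yr-1
wetland,DOC_runoff,areal,11,g C m-2 yr-1
wetland,litter,lineal,200,g C m-1 yr-1
surface_waters,CO2_evasion,areal,33,g C m-2 yr-1
surface_waters,CH4,areal,3,g C m-2 yr-1
surface_waters,sediment,areal,20,g C m-2 yr-1
surface_waters,runoff_export,areal,5,g C m-2 yr-1
forest,,area,3454059829.06,m2
wetland,,area,1791836734.69,m2
surface_waters,,area,850000000,m2
forest,,length,7805,km
wetland,,length,3469,km
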