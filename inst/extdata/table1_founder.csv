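species,target_island,main_source,distance_km,private_markers,propagules,population_diversity,regional_diversity,marker_proportion,sources_markers,sources_allocation
Angelica archangelica,Faroe Islands,NWEUR,570,1,9,0.82,0.79,0.76,2,1
Angelica archangelica,Iceland,NWEUR,775,1,8,0.82,0.78,0.81,2,2
Arctous alpinus,East Greenland,NWEUR,1270,1,13,0.86,0.76,0.57,3,1
Arenaria humifusa,East Greenland,SVALB,570,1,4,1.00,0.82,0.94,2,2
Avenella flexuosa,Iceland,NWEUR,775,1,11,0.96,0.94,0.79,2,2
Betula nana,East Greenland,ICE,280,0,13,0.73,0.94,0.82,3,1
Betula nana,Iceland,NWEUR,775,1,14,1.11,1.00,0.81,3,4
Betula nana,Svalbard,RUS,1000,1,7,0.68,0.70,0.59,2,3
Betula pubescens,Iceland,NWEUR,775,2,12,1.10,1.06,0.77,2,2
Carex bigelowii,East Greenland,ECAN,880,1,12,1.08,0.84,0.75,3,2
Carex bigelowii,Iceland,NWEUR,775,3,16,1.58,1.16,0.76,3,2
Cassiope tetragona,East Greenland,WGRE,360,1,14,1.00,1.06,1.04,4,2
Cassiope tetragona,Svalbard,EGRE,570,1,11,0.94,0.97,0.91,3,3
Chamerion angustifolium,Iceland,NWEUR,775,0,14,0.29,1.02,0.66,2,2
Dryas octopetala,Iceland,NWEUR,775,0,5,0.63,0.54,0.55,2,1
Dryas octopetala,Svalbard,RUS,1000,0,22,0.72,0.86,0.81,4,1
Empetrum nigrum,Faroe Islands,NWEUR,285,0,3,0.72,0.58,0.53,1,2
Empetrum nigrum,Iceland,NWEUR,775,0,6,0.75,0.65,0.63,1,3
Empetrum nigrum,Jan Mayen,ICE,555,0,3,0.30,0.20,0.64,1,1
Juniperus communis,Iceland,NWEUR,775,1,11,0.93,0.81,0.73,2,1
Loiseleuria procumbens,Iceland,NWEUR,775,1,9,0.93,0.97,0.93,3,2
Micranthes stellaris,Faroe Islands,NWEUR,285,0,1,1.38,1.05,0.71,1,1
Micranthes stellaris,Iceland,NWEUR,775,3,2,1.12,0.79,0.71,1,1
Ranunculus glacialis,Iceland,NWEUR,775,0,4,0.00,1.20,1.03,3,2
Ranunculus glacialis,Jan Mayen,ICE,555,0,1,1.00,0.14,0.86,1,1
Rubus chamaemorus,Svalbard,RUS,1000,0,5,0.47,0.51,0.62,1,1
Sagina caespitosa,Iceland,NWEUR,965,5,9,0.65,0.81,0.76,2,1
Sagina caespitosa,Jan Mayen,SVALB,875,1,11,0.35,0.30,0.68,2,2
Sagina caespitosa,Svalbard,NOR,640,1,3,0.26,0.22,0.64,2,1
Salix herbacea,East Greenland,JM,450,0,14,0.73,0.85,1.03,3,2
Salix herbacea,Iceland,NWEUR,775,1,16,0.74,0.67,0.64,5,3
Salix herbacea,Jan Mayen,ICE,555,0,13,0.97,0.92,0.79,3,2
Salix herbacea,Svalbard,NWEUR,1000,1,12,0.67,0.70,0.57,3,1
Saxifraga rivularis,Iceland,NWEUR,775,0,7,1.09,0.83,0.81,2,3
Saxifraga rivularis,Jan Mayen,SVALB,945,0,4,0.26,0.21,0.55,1,1
Sibbaldia procumbens,East Greenland,ECAN,360,0,5,0.77,0.69,0.80,2,2
Sibbaldia procumbens,Faroe Islands,ICE,425,0,3,0.91,0.75,0.82,2,1
Sibbaldia procumbens,Iceland,EGRE,280,1,5,0.55,0.70,0.98,2,1
Sibbaldia procumbens,Jan Mayen,ICE,555,0,2,0.55,0.46,0.77,1,1
Sibbaldia procumbens,Svalbard,NWEUR,640,0,2,0.00,0.00,0.75,1,1
Thalictrum alpinum,Faroe Islands,NWEUR,285,0,14,1.12,0.94,0.68,3,1
Thalictrum alpinum,Iceland,NWEUR,775,0,12,1.18,0.99,0.68,2,1
Vaccinium uliginosum,East Greenland,WGRE,360,0,10,1.15,1.12,1.10,3,4
Vaccinium uliginosum,Iceland,NWEUR,775,0,11,1.05,0.90,0.75,2,3
Vaccinium uliginosum,Svalbard,RUS,1000,0,9,0.33,0.84,0.67,2,2
Vaccinium vitis-idaea,Iceland,NWEUR,775,0,6,1.07,0.89,0.73,2,3
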