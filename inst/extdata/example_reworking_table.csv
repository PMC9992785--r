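taxon,group,reworking_rate,burrow_radius,burrow_depth,mode,fracture_toughness
Ensis_like_bivalve,molluscs,120,0.004,0.35,both,3
Nereis_like_polychaete,polychaetes,0.5,0.0012,0.04,crack_propagation,2
Ray_pit_feeder,macro_epifauna,0.0005,0.2,0.18,excavation,1
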