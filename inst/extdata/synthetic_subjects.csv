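"subject_id","site_id","gender","age_at_implant","age_at_moderate_loss","age_at_profound_loss","etiology","device_brand","electrode","processor","implanted_side","surgical_approach","preop_ha_in_implanted_ear","education_years"
"S0001","site_1","male",27.088234049055,0,0,"other","Cochlear","standard","gen3","right","round_window",FALSE,15.5941566353902
"S0002","site_7","male",43.4880574198059,,35.367430598028,"otosclerosis","Cochlear","perimodiolar","gen2","right","round_window",FALSE,21.4523493823045
"S0003","site_3","female",58.7731743117545,,57.8025342982126,"unknown","Cochlear","lateral_wall","gen1","right","cochleostomy",FALSE,14.8617661716593
"S0004","site_2","male",56.8029619490311,,49.0028807484695,"genetic","AB","perimodiolar","gen2","right","cochleostomy",FALSE,13.8567611331636
"S0005","site_1","female",47.6773314839328,36.8384552271944,40.2675494612102,"unknown","Cochlear","standard","gen3","right","cochleostomy",FALSE,12.1486751617969
"S0006","site_1","male",58.3889548335821,23.7012578213384,52.40852049815,"meningitis","Neurelec","standard","gen3","right","cochleostomy",FALSE,18.2381320886918
"S0007","site_1","female",70.2743720535638,55.8649042044851,60.7904636167074,"other","AB","lateral_wall","gen3","left","round_window",TRUE,14.0459422304053
"S0008","site_1","female",75.3595870747589,71.2345695818236,72.8742970428788,"unknown","Neurelec","perimodiolar","gen3","left","cochleostomy",FALSE,14.6740580827064
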