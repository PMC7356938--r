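"table","column","type","units","allowed","required"
"subjects","subject_id","character","","",TRUE
"subjects","site_id","character","","",FALSE
"subjects","gender","character","","male|female",TRUE
"subjects","age_at_implant","numeric","years",">=0",TRUE
"subjects","age_at_moderate_loss","numeric","years",">=0 or NA",FALSE
"subjects","age_at_profound_loss","numeric","years",">=0 or NA",FALSE
"subjects","etiology","character","","",FALSE
"subjects","device_brand","character","","",FALSE
"subjects","electrode","character","","",FALSE
"subjects","processor","character","","",FALSE
"subjects","implanted_side","character","","left|right",FALSE
"subjects","surgical_approach","character","","cochleostomy|round_window",FALSE
"subjects","preop_ha_in_implanted_ear","logical","","TRUE|FALSE",FALSE
"subjects","education_years","numeric","years",">=0 or NA",FALSE
"sessions","subject_id","character","","",TRUE
"sessions","session_id","character","","",TRUE
"sessions","phase","character","","pre|post",TRUE
"sessions","months_since_surgery","numeric","months",">=0 (0 for pre)",TRUE
"sessions","ha_verification","character","","in_ear|aided_unaided_thresholds|aided_unaided_speech|clinician_report|unknown",TRUE
"sessions","thr_250hz","numeric","dB HL","[-10, 130] or NA",FALSE
"sessions","thr_500hz","numeric","dB HL","[-10, 130] or NA",FALSE
"sessions","thr_1000hz","numeric","dB HL","[-10, 130] or NA",FALSE
"sessions","thr_2000hz","numeric","dB HL","[-10, 130] or NA",FALSE
"sessions","thr_4000hz","numeric","dB HL","[-10, 130] or NA",FALSE
"sessions","implanted_test_id","character","","registered test id",FALSE
"sessions","implanted_pct","numeric","% correct","[0, 100] or NA",FALSE
"sessions","implanted_cnt","logical","","TRUE|FALSE",FALSE
"sessions","implanted_n_lists","integer","lists",">=1",FALSE
"sessions","nonimplanted_test_id","character","","registered test id",FALSE
"sessions","nonimplanted_pct","numeric","% correct","[0, 100] or NA",FALSE
"sessions","nonimplanted_cnt","logical","","TRUE|FALSE",FALSE
"sessions","nonimplanted_n_lists","integer","lists",">=1",FALSE
"sessions","bilateral_test_id","character","","registered test id",FALSE
"sessions","bilateral_pct","numeric","% correct","[0, 100] or NA",FALSE
"sessions","bilateral_cnt","logical","","TRUE|FALSE",FALSE
"sessions","bilateral_n_lists","integer","lists",">=1",FALSE
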