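"subject_id","session_id","phase","months_since_surgery","ha_verification","thr_250hz","thr_500hz","thr_1000hz","thr_2000hz","thr_4000hz","implanted_test_id","implanted_pct","implanted_cnt","implanted_n_lists","nonimplanted_test_id","nonimplanted_pct","nonimplanted_cnt","nonimplanted_n_lists","bilateral_test_id","bilateral_pct","bilateral_cnt","bilateral_n_lists"
"S0001","E00","pre",0,"aided_unaided_thresholds",47.0037083819501,57.0037083819501,62.0037083819501,67.0037083819501,77.0037083819501,"sent_kw_cuny",7.5,FALSE,1,"sent_kw_cuny",40,FALSE,1,"sent_kw_cuny",30,FALSE,1
"S0001","E01","post",15.29,"aided_unaided_thresholds",48.3564877568589,58.3564877568589,63.3564877568589,68.3564877568589,78.3564877568589,"sent_kw_cuny",72.5,FALSE,1,"sent_kw_cuny",25,FALSE,1,"sent_kw_cuny",70,FALSE,1
"S0001","E02","post",61.5,"aided_unaided_thresholds",52.4449073065343,62.4449073065343,67.4449073065343,72.4449073065343,82.4449073065343,"sent_kw_cuny",72.5,FALSE,1,"sent_kw_cuny",37.5,FALSE,1,"sent_kw_cuny",80,FALSE,1
"S0002","E00","pre",0,"aided_unaided_thresholds",45.926533001038,55.926533001038,60.926533001038,65.926533001038,75.926533001038,"word_w50",2,FALSE,1,"word_w50",50,FALSE,1,"word_w50",,TRUE,1
"S0002","E01","post",15.26,"aided_unaided_thresholds",45.926533001038,55.926533001038,60.926533001038,65.926533001038,75.926533001038,"word_w50",78,FALSE,1,"word_w50",44,FALSE,1,"word_w50",88,FALSE,1
"S0002","E02","post",23.08,"aided_unaided_thresholds",45.926533001038,55.926533001038,60.926533001038,65.926533001038,75.926533001038,"word_w50",86,FALSE,2,"word_w50",35,FALSE,2,"word_w50",86,FALSE,2
"S0003","E00","pre",0,"unknown",64.357055220996,74.357055220996,79.357055220996,84.357055220996,94.357055220996,"word_w25",4,FALSE,1,"word_w25",32,FALSE,1,"word_w25",60,FALSE,1
"S0003","E01","post",35.42,"unknown",64.357055220996,74.357055220996,79.357055220996,84.357055220996,94.357055220996,"word_w25",50,FALSE,2,"word_w25",20,FALSE,2,"word_w25",52,FALSE,2
"S0004","E00","pre",0,"clinician_report",60.6687648059894,70.6687648059894,75.6687648059894,80.6687648059894,90.6687648059894,"word_w50",12,FALSE,1,"word_w50",40,FALSE,1,"word_w50",54,FALSE,1
"S0004","E01","post",16.02,"clinician_report",61.9517638209151,71.9517638209151,76.9517638209151,81.9517638209151,91.9517638209151,"word_w50",60,FALSE,1,"word_w50",46,FALSE,1,"word_w50",66,FALSE,1
"S0004","E02","post",25.56,"clinician_report",62.715796942163,72.715796942163,77.715796942163,82.715796942163,92.715796942163,"word_w50",63,FALSE,2,"word_w50",49,FALSE,2,"word_w50",79,FALSE,2
"S0004","E03","post",27.88,"clinician_report",62.9015995460723,72.9015995460723,77.9015995460723,82.9015995460723,92.9015995460723,"word_w50",66,FALSE,1,"word_w50",46,FALSE,1,"word_w50",68,FALSE,1
"S0005","E00","pre",0,"aided_unaided_thresholds",47.5208209536847,57.5208209536847,62.5208209536847,67.5208209536847,77.5208209536847,"word_w50",,TRUE,1,"word_w50",66,FALSE,1,"word_w50",,TRUE,1
"S0005","E01","post",17.18,"aided_unaided_thresholds",47.9328507762981,57.9328507762981,62.9328507762981,67.9328507762981,77.9328507762981,"word_w50",72,FALSE,1,"word_w50",90,FALSE,1,"word_w50",94,FALSE,1
"S0005","E02","post",52.2,"aided_unaided_thresholds",48.7727392738488,58.7727392738488,63.7727392738488,68.7727392738488,78.7727392738488,"word_w50",60,FALSE,1,"word_w50",84,FALSE,1,"word_w50",96,FALSE,1
"S0006","E00","pre",0,"aided_unaided_thresholds",59.9565390289705,69.9565390289705,74.9565390289705,79.9565390289705,89.9565390289705,"sent_kw_cuny",12.5,FALSE,1,"sent_kw_cuny",10,FALSE,1,"sent_kw_cuny",5,FALSE,1
"S0006","E01","post",6.77,"aided_unaided_thresholds",60.1326534344284,70.1326534344284,75.1326534344284,80.1326534344284,90.1326534344284,"sent_kw_cuny",60,FALSE,1,"sent_kw_cuny",7.5,FALSE,1,"sent_kw_cuny",70,FALSE,1
"S0006","E02","post",36.18,"aided_unaided_thresholds",60.8977235473558,70.8977235473558,75.8977235473558,80.8977235473558,90.8977235473558,"sent_kw_cuny",47.5,FALSE,2,"sent_kw_cuny",5,FALSE,2,"sent_kw_cuny",45,FALSE,2
"S0006","E03","post",101,"aided_unaided_thresholds",62.5839474412677,72.5839474412677,77.5839474412677,82.5839474412677,92.5839474412677,"sent_kw_cuny",47.5,FALSE,1,"sent_kw_cuny",5,FALSE,1,"sent_kw_cuny",37.5,FALSE,1
"S0006","E04","post",113.92,"aided_unaided_thresholds",62.9200476064843,72.9200476064843,77.9200476064843,82.9200476064843,92.9200476064843,"sent_kw_cuny",62.5,FALSE,1,"sent_kw_cuny",5,FALSE,1,"sent_kw_cuny",50,FALSE,1
"S0007","E00","pre",0,"aided_unaided_thresholds",54.3919090518203,64.3919090518203,69.3919090518203,74.3919090518203,84.3919090518203,"sent_kw_cuny",5,FALSE,2,"sent_kw_cuny",37.5,FALSE,2,"sent_kw_cuny",,TRUE,2
"S0007","E01","post",17.67,"aided_unaided_thresholds",54.3919090518203,64.3919090518203,69.3919090518203,74.3919090518203,84.3919090518203,"sent_kw_cuny",42.5,FALSE,2,"sent_kw_cuny",52.5,FALSE,2,"sent_kw_cuny",60,FALSE,2
"S0007","E02","post",130.44,"aided_unaided_thresholds",54.3919090518203,64.3919090518203,69.3919090518203,74.3919090518203,84.3919090518203,"sent_kw_cuny",30,FALSE,1,"sent_kw_cuny",45,FALSE,1,"sent_kw_cuny",45,FALSE,1
"S0008","E00","pre",0,"clinician_report",53.5222347965712,63.5222347965712,68.5222347965712,73.5222347965712,83.5222347965712,"sent_kw_cuny",,TRUE,1,"sent_kw_cuny",62.5,FALSE,1,"sent_kw_cuny",60,FALSE,1
"S0008","E01","post",7.85,"clinician_report",53.5222347965712,63.5222347965712,68.5222347965712,73.5222347965712,83.5222347965712,"sent_kw_cuny",80,FALSE,1,"sent_kw_cuny",45,FALSE,1,"sent_kw_cuny",90,FALSE,1
"S0008","E02","post",11.19,"clinician_report",53.5222347965712,63.5222347965712,68.5222347965712,73.5222347965712,83.5222347965712,"sent_kw_cuny",80,FALSE,1,"sent_kw_cuny",52.5,FALSE,1,"sent_kw_cuny",87.5,FALSE,1
"S0008","E03","post",12.09,"clinician_report",53.5222347965712,63.5222347965712,68.5222347965712,73.5222347965712,83.5222347965712,"sent_kw_cuny",85,FALSE,1,"sent_kw_cuny",37.5,FALSE,1,"sent_kw_cuny",82.5,FALSE,1
"S0008","E04","post",19.66,"clinician_report",53.5222347965712,63.5222347965712,68.5222347965712,73.5222347965712,83.5222347965712,"sent_kw_cuny",90,FALSE,1,"sent_kw_cuny",57.5,FALSE,1,"sent_kw_cuny",87.5,FALSE,1
"S0008","E05","post",30.54,"clinician_report",53.5222347965712,63.5222347965712,68.5222347965712,73.5222347965712,83.5222347965712,"sent_kw_cuny",80,FALSE,2,"sent_kw_cuny",40,FALSE,2,"sent_kw_cuny",90,FALSE,2
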