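{"death":{"class":"lgl_cncpt","description":"in-hospital death flag","category":"outcome","omopid":4306655,"target":"ts_tbl","aggregate":"any","sources":{"mimic":[{"table":"events","sub_var":"itemid","ids":[50402],"class":"sel_itm"}],"eicu":[{"table":"events","sub_var":"itemid","ids":[50403],"class":"sel_itm"}],"aumc":[{"table":"events","sub_var":"itemid","ids":[50404],"class":"sel_itm"}],"hirid":[{"table":"events","sub_var":"itemid","ids":[50405],"class":"sel_itm"}],"miiv":[{"table":"events","sub_var":"itemid","ids":[50406],"class":"sel_itm"}],"eav_absolute":[{"table":"admissions","class":"col_itm","value_column":"deathtime","callback":"death_flag"}],"wide_relative":[{"table":"unitstays","class":"col_itm","value_column":"deathoffset","callback":"death_flag"}],"eav_relative":[{"table":"admissions","class":"col_itm","value_column":"dateofdeath","callback":"death_flag"}]}},"disch":{"class":"fct_cncpt","description":"discharge destination","category":"outcome","levels":["home","expired","transfer"],"target":"id_tbl","aggregate":"first","sources":{"mimic":[{"table":"events","sub_var":"itemid","ids":[50407],"class":"sel_itm"}],"eicu":[{"table":"events","sub_var":"itemid","ids":[50408],"class":"sel_itm"}],"aumc":[{"table":"events","sub_var":"itemid","ids":[50409],"class":"sel_itm"}],"miiv":[{"table":"events","sub_var":"itemid","ids":[50410],"class":"sel_itm"}],"eav_absolute":[{"table":"chartevents","sub_var":"itemid","ids":[90089],"class":"sel_itm"}],"wide_relative":[{"table":"misc","sub_var":"conceptcode","ids":["C90089"],"class":"sel_itm"}],"eav_relative":[{"table":"events","sub_var":"itemid","ids":[90089],"class":"sel_itm"}]}},"rrt":{"class":"lgl_cncpt","description":"renal replacement therapy","category":"outcome","target":"ts_tbl","aggregate":"any","sources":{"mimic":[{"table":"events","sub_var":"itemid","ids":[50411],"class":"sel_itm"}],"eicu":[{"table":"events","sub_var":"itemid","ids":[50412],"class":"sel_itm"}],"aumc":[{"table":"events","sub_var":"itemid","ids":[50413],"class":"sel_itm"}],"miiv":[{"table":"events","sub_var":"itemid","ids":[50414],"class":"sel_itm"}],"eav_absolute":[{"table":"chartevents","sub_var":"itemid","ids":[90090],"class":"sel_itm"}],"wide_relative":[{"table":"misc","sub_var":"conceptcode","ids":["C90090"],"class":"sel_itm"}],"eav_relative":[{"table":"events","sub_var":"itemid","ids":[90090],"class":"sel_itm"}]}},"trach":{"class":"lgl_cncpt","description":"tracheostomy","category":"outcome","target":"ts_tbl","aggregate":"any","sources":{"mimic":[{"table":"events","sub_var":"itemid","ids":[50415],"class":"sel_itm"}],"eicu":[{"table":"events","sub_var":"itemid","ids":[50416],"class":"sel_itm"}],"aumc":[{"table":"events","sub_var":"itemid","ids":[50417],"class":"sel_itm"}],"miiv":[{"table":"events","sub_var":"itemid","ids":[50418],"class":"sel_itm"}],"eav_absolute":[{"table":"chartevents","sub_var":"itemid","ids":[90091],"class":"sel_itm"}],"wide_relative":[{"table":"misc","sub_var":"conceptcode","ids":["C90091"],"class":"sel_itm"}],"eav_relative":[{"table":"events","sub_var":"itemid","ids":[90091],"class":"sel_itm"}]}},"dnr":{"class":"lgl_cncpt","description":"do-not-resuscitate order","category":"outcome","target":"ts_tbl","aggregate":"any","sources":{"mimic":[{"table":"events","sub_var":"itemid","ids":[50419],"class":"sel_itm"}],"eicu":[{"table":"events","sub_var":"itemid","ids":[50420],"class":"sel_itm"}],"aumc":[{"table":"events","sub_var":"itemid","ids":[50421],"class":"sel_itm"}],"miiv":[{"table":"events","sub_var":"itemid","ids":[50422],"class":"sel_itm"}],"eav_absolute":[{"table":"chartevents","sub_var":"itemid","ids":[90092],"class":"sel_itm"}],"wide_relative":[{"table":"misc","sub_var":"conceptcode","ids":["C90092"],"class":"sel_itm"}],"eav_relative":[{"table":"events","sub_var":"itemid","ids":[90092],"class":"sel_itm"}]}},"sofa_resp":{"class":"rec_cncpt","description":"SOFA respiratory component","category":"outcome","concepts":["pafi","vent_ind"],"callback":"sofa_resp_cb","target":"ts_tbl"},"sofa_coag":{"class":"rec_cncpt","description":"SOFA coagulation component","category":"outcome","concepts":["plt"],"callback":"sofa_coag_cb","target":"ts_tbl"},"sofa_liver":{"class":"rec_cncpt","description":"SOFA liver component","category":"outcome","concepts":["bili"],"callback":"sofa_liver_cb","target":"ts_tbl"},"sofa_cardio":{"class":"rec_cncpt","description":"SOFA cardiovascular component","category":"outcome","concepts":["map","dopa_rate","dobu_rate","epi_rate","norepi_rate"],"callback":"sofa_cardio_cb","target":"ts_tbl"},"sofa_cns":{"class":"rec_cncpt","description":"SOFA central nervous system component","category":"outcome","concepts":["gcs"],"callback":"sofa_cns_cb","target":"ts_tbl"},"sofa_renal":{"class":"rec_cncpt","description":"SOFA renal component","category":"outcome","concepts":["crea"],"callback":"sofa_renal_cb","target":"ts_tbl"},"sofa":{"class":"rec_cncpt","description":"SOFA total score","category":"outcome","concepts":["sofa_resp","sofa_coag","sofa_liver","sofa_cardio","sofa_cns","sofa_renal"],"callback":"sofa_cb","target":"ts_tbl","omopid":1616852},"susp_inf":{"class":"rec_cncpt","description":"suspected infection onset","category":"outcome","concepts":["abx","samp"],"callback":"susp_inf_cb","target":"ts_tbl"},"sep3":{"class":"rec_cncpt","description":"Sepsis-3 label","category":"outcome","concepts":["sofa","susp_inf"],"callback":"sep3_cb","target":"ts_tbl","omopid":132797},"qsofa":{"class":"rec_cncpt","description":"quick SOFA score","category":"outcome","concepts":["sbp","resp","gcs"],"callback":"qsofa_cb","target":"ts_tbl"},"sirs":{"class":"rec_cncpt","description":"SIRS criteria count","category":"outcome","concepts":["temp","hr","resp","wbc"],"callback":"sirs_cb","target":"ts_tbl"},"mews":{"class":"rec_cncpt","description":"modified early warning score (simplified)","category":"outcome","concepts":["sbp","hr","resp","temp","avpu"],"callback":"mews_cb","target":"ts_tbl"},"news":{"class":"rec_cncpt","description":"national early warning score (simplified)","category":"outcome","concepts":["resp","o2sat","temp","sbp","hr"],"callback":"news_cb","target":"ts_tbl"},"aki":{"class":"rec_cncpt","description":"acute kidney injury flag (creatinine criteria)","category":"outcome","concepts":["crea"],"callback":"aki_cb","target":"ts_tbl"}}
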