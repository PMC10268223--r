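{"fio2":{"class":"num_cncpt","description":"inspired oxygen fraction","category":"respiratory","unit":["%"],"min":21,"max":100,"target":"ts_tbl","sources":{"mimic":[{"table":"events","sub_var":"itemid","ids":[50255],"class":"sel_itm"}],"eicu":[{"table":"events","sub_var":"itemid","ids":[50256],"class":"sel_itm"}],"aumc":[{"table":"events","sub_var":"itemid","ids":[50257],"class":"sel_itm"}],"hirid":[{"table":"events","sub_var":"itemid","ids":[50258],"class":"sel_itm"}],"miiv":[{"table":"events","sub_var":"itemid","ids":[50259],"class":"sel_itm"}],"eav_absolute":[{"table":"chartevents","sub_var":"itemid","ids":[90056],"class":"sel_itm"}],"wide_relative":[{"table":"misc","sub_var":"conceptcode","ids":["C90056"],"class":"sel_itm"}],"eav_relative":[{"table":"events","sub_var":"itemid","ids":[90056],"class":"sel_itm"}]}},"o2sat":{"class":"num_cncpt","description":"oxygen saturation","category":"respiratory","unit":["%"],"min":0,"max":100,"omopid":4196147,"target":"ts_tbl","sources":{"mimic":[{"table":"events","sub_var":"itemid","ids":[50260],"class":"sel_itm"}],"eicu":[{"table":"events","sub_var":"itemid","ids":[50261],"class":"sel_itm"}],"aumc":[{"table":"events","sub_var":"itemid","ids":[50262],"class":"sel_itm"}],"hirid":[{"table":"events","sub_var":"itemid","ids":[50263],"class":"sel_itm"}],"miiv":[{"table":"events","sub_var":"itemid","ids":[50264],"class":"sel_itm"}],"eav_absolute":[{"table":"chartevents","sub_var":"itemid","ids":[90057],"class":"sel_itm"}],"wide_relative":[{"table":"misc","sub_var":"conceptcode","ids":["C90057"],"class":"sel_itm"}],"eav_relative":[{"table":"events","sub_var":"itemid","ids":[90057],"class":"sel_itm"}]}},"resp":{"class":"num_cncpt","description":"respiratory rate","category":"respiratory","unit":["/min","insp/min"],"min":0,"max":120,"omopid":4313591,"target":"ts_tbl","sources":{"mimic":[{"table":"events","sub_var":"itemid","ids":[50265],"class":"sel_itm"}],"eicu":[{"table":"events","sub_var":"itemid","ids":[50266],"class":"sel_itm"}],"aumc":[{"table":"events","sub_var":"itemid","ids":[50267],"class":"sel_itm"}],"hirid":[{"table":"events","sub_var":"itemid","ids":[50268],"class":"sel_itm"}],"miiv":[{"table":"events","sub_var":"itemid","ids":[50269],"class":"sel_itm"}],"eav_absolute":[{"table":"chartevents","sub_var":"itemid","ids":[90058],"class":"sel_itm"}],"wide_relative":[{"table":"misc","sub_var":"conceptcode","ids":["C90058"],"class":"sel_itm"}],"eav_relative":[{"table":"events","sub_var":"itemid","ids":[90058],"class":"sel_itm"}]}},"peep":{"class":"num_cncpt","description":"positive end-expiratory pressure","category":"respiratory","unit":["cmH2O"],"min":0,"max":50,"target":"ts_tbl","sources":{"mimic":[{"table":"events","sub_var":"itemid","ids":[50270],"class":"sel_itm"}],"eicu":[{"table":"events","sub_var":"itemid","ids":[50271],"class":"sel_itm"}],"aumc":[{"table":"events","sub_var":"itemid","ids":[50272],"class":"sel_itm"}],"hirid":[{"table":"events","sub_var":"itemid","ids":[50273],"class":"sel_itm"}],"miiv":[{"table":"events","sub_var":"itemid","ids":[50274],"class":"sel_itm"}],"eav_absolute":[{"table":"chartevents","sub_var":"itemid","ids":[90059],"class":"sel_itm"}],"wide_relative":[{"table":"misc","sub_var":"conceptcode","ids":["C90059"],"class":"sel_itm"}],"eav_relative":[{"table":"events","sub_var":"itemid","ids":[90059],"class":"sel_itm"}]}},"tidal_vol":{"class":"num_cncpt","description":"tidal volume","category":"respiratory","unit":["mL"],"min":0,"max":2000,"target":"ts_tbl","sources":{"mimic":[{"table":"events","sub_var":"itemid","ids":[50275],"class":"sel_itm"}],"eicu":[{"table":"events","sub_var":"itemid","ids":[50276],"class":"sel_itm"}],"aumc":[{"table":"events","sub_var":"itemid","ids":[50277],"class":"sel_itm"}],"hirid":[{"table":"events","sub_var":"itemid","ids":[50278],"class":"sel_itm"}],"miiv":[{"table":"events","sub_var":"itemid","ids":[50279],"class":"sel_itm"}],"eav_absolute":[{"table":"chartevents","sub_var":"itemid","ids":[90060],"class":"sel_itm"}],"wide_relative":[{"table":"misc","sub_var":"conceptcode","ids":["C90060"],"class":"sel_itm"}],"eav_relative":[{"table":"events","sub_var":"itemid","ids":[90060],"class":"sel_itm"}]}},"minute_vol":{"class":"num_cncpt","description":"minute ventilation","category":"respiratory","unit":["L/min"],"min":0,"max":50,"target":"ts_tbl","sources":{"mimic":[{"table":"events","sub_var":"itemid","ids":[50280],"class":"sel_itm"}],"eicu":[{"table":"events","sub_var":"itemid","ids":[50281],"class":"sel_itm"}],"aumc":[{"table":"events","sub_var":"itemid","ids":[50282],"class":"sel_itm"}],"hirid":[{"table":"events","sub_var":"itemid","ids":[50283],"class":"sel_itm"}],"miiv":[{"table":"events","sub_var":"itemid","ids":[50284],"class":"sel_itm"}],"eav_absolute":[{"table":"chartevents","sub_var":"itemid","ids":[90061],"class":"sel_itm"}],"wide_relative":[{"table":"misc","sub_var":"conceptcode","ids":["C90061"],"class":"sel_itm"}],"eav_relative":[{"table":"events","sub_var":"itemid","ids":[90061],"class":"sel_itm"}]}},"mech_vent":{"class":"fct_cncpt","description":"mechanical ventilation episode","category":"respiratory","levels":["invasive","noninvasive"],"target":"win_tbl","aggregate":"first","sources":{"mimic":[{"table":"events","sub_var":"itemid","ids":[50285],"class":"sel_itm"}],"eicu":[{"table":"events","sub_var":"itemid","ids":[50286],"class":"sel_itm"}],"aumc":[{"table":"events","sub_var":"itemid","ids":[50287],"class":"sel_itm"}],"hirid":[{"table":"events","sub_var":"itemid","ids":[50288],"class":"sel_itm"}],"miiv":[{"table":"events","sub_var":"itemid","ids":[50289],"class":"sel_itm"}],"eav_absolute":[{"table":"ventevents","class":"col_itm"}],"wide_relative":[{"table":"vent","class":"col_itm"}],"eav_relative":[{"table":"vent","class":"col_itm"}]}},"supp_o2":{"class":"lgl_cncpt","description":"supplemental oxygen","category":"respiratory","target":"ts_tbl","aggregate":"any","sources":{"mimic":[{"table":"events","sub_var":"itemid","ids":[50290],"class":"sel_itm"}],"eicu":[{"table":"events","sub_var":"itemid","ids":[50291],"class":"sel_itm"}],"aumc":[{"table":"events","sub_var":"itemid","ids":[50292],"class":"sel_itm"}],"miiv":[{"table":"events","sub_var":"itemid","ids":[50293],"class":"sel_itm"}],"eav_absolute":[{"table":"chartevents","sub_var":"itemid","ids":[90063],"class":"sel_itm"}],"wide_relative":[{"table":"misc","sub_var":"conceptcode","ids":["C90063"],"class":"sel_itm"}],"eav_relative":[{"table":"events","sub_var":"itemid","ids":[90063],"class":"sel_itm"}]}},"vent_ind":{"class":"rec_cncpt","description":"ventilation indicator","category":"respiratory","concepts":["mech_vent"],"callback":"vent_ind_cb","target":"ts_tbl"},"safi":{"class":"rec_cncpt","description":"SpO2/FiO2 ratio","category":"respiratory","concepts":["o2sat","fio2"],"callback":"safi_cb","target":"ts_tbl"}}
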