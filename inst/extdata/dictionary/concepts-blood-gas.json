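{"po2":{"class":"num_cncpt","description":"arterial oxygen partial pressure","category":"blood gas","unit":["mmHg"],"min":0,"max":700,"omopid":4094581,"target":"ts_tbl","sources":{"mimic":[{"table":"events","sub_var":"itemid","ids":[50001],"class":"sel_itm"}],"eicu":[{"table":"events","sub_var":"itemid","ids":[50002],"class":"sel_itm"}],"aumc":[{"table":"events","sub_var":"itemid","ids":[50003],"class":"sel_itm"}],"hirid":[{"table":"events","sub_var":"itemid","ids":[50004],"class":"sel_itm"}],"miiv":[{"table":"events","sub_var":"itemid","ids":[50005],"class":"sel_itm"}],"eav_absolute":[{"table":"chartevents","sub_var":"itemid","ids":[90001],"class":"sel_itm"}],"wide_relative":[{"table":"misc","sub_var":"conceptcode","ids":["C90001"],"class":"sel_itm"}],"eav_relative":[{"table":"events","sub_var":"itemid","ids":[90001],"class":"sel_itm"}]}},"pco2":{"class":"num_cncpt","description":"arterial carbon dioxide partial pressure","category":"blood gas","unit":["mmHg"],"min":0,"max":250,"omopid":4097882,"target":"ts_tbl","sources":{"mimic":[{"table":"events","sub_var":"itemid","ids":[50006],"class":"sel_itm"}],"eicu":[{"table":"events","sub_var":"itemid","ids":[50007],"class":"sel_itm"}],"aumc":[{"table":"events","sub_var":"itemid","ids":[50008],"class":"sel_itm"}],"hirid":[{"table":"events","sub_var":"itemid","ids":[50009],"class":"sel_itm"}],"miiv":[{"table":"events","sub_var":"itemid","ids":[50010],"class":"sel_itm"}],"eav_absolute":[{"table":"chartevents","sub_var":"itemid","ids":[90002],"class":"sel_itm"}],"wide_relative":[{"table":"misc","sub_var":"conceptcode","ids":["C90002"],"class":"sel_itm"}],"eav_relative":[{"table":"events","sub_var":"itemid","ids":[90002],"class":"sel_itm"}]}},"ph":{"class":"num_cncpt","description":"arterial pH","category":"blood gas","min":6.5,"max":8,"omopid":4097822,"target":"ts_tbl","sources":{"mimic":[{"table":"events","sub_var":"itemid","ids":[50011],"class":"sel_itm"}],"eicu":[{"table":"events","sub_var":"itemid","ids":[50012],"class":"sel_itm"}],"aumc":[{"table":"events","sub_var":"itemid","ids":[50013],"class":"sel_itm"}],"hirid":[{"table":"events","sub_var":"itemid","ids":[50014],"class":"sel_itm"}],"miiv":[{"table":"events","sub_var":"itemid","ids":[50015],"class":"sel_itm"}],"eav_absolute":[{"table":"chartevents","sub_var":"itemid","ids":[90003],"class":"sel_itm"}],"wide_relative":[{"table":"misc","sub_var":"conceptcode","ids":["C90003"],"class":"sel_itm"}],"eav_relative":[{"table":"events","sub_var":"itemid","ids":[90003],"class":"sel_itm"}]}},"be":{"class":"num_cncpt","description":"base excess","category":"blood gas","unit":["mEq/L"],"min":-50,"max":50,"target":"ts_tbl","sources":{"mimic":[{"table":"events","sub_var":"itemid","ids":[50016],"class":"sel_itm"}],"aumc":[{"table":"events","sub_var":"itemid","ids":[50017],"class":"sel_itm"}],"hirid":[{"table":"events","sub_var":"itemid","ids":[50018],"class":"sel_itm"}],"miiv":[{"table":"events","sub_var":"itemid","ids":[50019],"class":"sel_itm"}],"eav_absolute":[{"table":"chartevents","sub_var":"itemid","ids":[90004],"class":"sel_itm"}],"wide_relative":[{"table":"misc","sub_var":"conceptcode","ids":["C90004"],"class":"sel_itm"}],"eav_relative":[{"table":"events","sub_var":"itemid","ids":[90004],"class":"sel_itm"}]}},"bicar":{"class":"num_cncpt","description":"bicarbonate","category":"blood gas","unit":["mEq/L","mmol/L"],"min":0,"max":60,"omopid":4194291,"target":"ts_tbl","sources":{"mimic":[{"table":"events","sub_var":"itemid","ids":[50020],"class":"sel_itm"}],"eicu":[{"table":"events","sub_var":"itemid","ids":[50021],"class":"sel_itm"}],"aumc":[{"table":"events","sub_var":"itemid","ids":[50022],"class":"sel_itm"}],"hirid":[{"table":"events","sub_var":"itemid","ids":[50023],"class":"sel_itm"}],"miiv":[{"table":"events","sub_var":"itemid","ids":[50024],"class":"sel_itm"}],"eav_absolute":[{"table":"chartevents","sub_var":"itemid","ids":[90005],"class":"sel_itm"}],"wide_relative":[{"table":"misc","sub_var":"conceptcode","ids":["C90005"],"class":"sel_itm"}],"eav_relative":[{"table":"events","sub_var":"itemid","ids":[90005],"class":"sel_itm"}]}},"lact":{"class":"num_cncpt","description":"lactate","category":"blood gas","unit":["mmol/L"],"min":0,"max":50,"omopid":4191725,"target":"ts_tbl","sources":{"mimic":[{"table":"events","sub_var":"itemid","ids":[50025],"class":"sel_itm"}],"eicu":[{"table":"events","sub_var":"itemid","ids":[50026],"class":"sel_itm"}],"aumc":[{"table":"events","sub_var":"itemid","ids":[50027],"class":"sel_itm"}],"hirid":[{"table":"events","sub_var":"itemid","ids":[50028],"class":"sel_itm"}],"miiv":[{"table":"events","sub_var":"itemid","ids":[50029],"class":"sel_itm"}],"eav_absolute":[{"table":"labevents","sub_var":"itemid","ids":[50813],"class":"sel_itm"}],"wide_relative":[{"table":"lab","class":"col_itm","value_column":"lact"}],"eav_relative":[{"table":"events","sub_var":"itemid","ids":[10053],"class":"sel_itm"}]}},"methb":{"class":"num_cncpt","description":"methemoglobin fraction","category":"blood gas","unit":["%"],"min":0,"max":100,"target":"ts_tbl","sources":{"mimic":[{"table":"events","sub_var":"itemid","ids":[50030],"class":"sel_itm"}],"aumc":[{"table":"events","sub_var":"itemid","ids":[50031],"class":"sel_itm"}],"hirid":[{"table":"events","sub_var":"itemid","ids":[50032],"class":"sel_itm"}],"eav_absolute":[{"table":"chartevents","sub_var":"itemid","ids":[90007],"class":"sel_itm"}],"wide_relative":[{"table":"misc","sub_var":"conceptcode","ids":["C90007"],"class":"sel_itm"}],"eav_relative":[{"table":"events","sub_var":"itemid","ids":[90007],"class":"sel_itm"}]}},"cai":{"class":"num_cncpt","description":"ionized calcium","category":"blood gas","unit":["mmol/L"],"min":0,"max":5,"target":"ts_tbl","sources":{"mimic":[{"table":"events","sub_var":"itemid","ids":[50033],"class":"sel_itm"}],"aumc":[{"table":"events","sub_var":"itemid","ids":[50034],"class":"sel_itm"}],"hirid":[{"table":"events","sub_var":"itemid","ids":[50035],"class":"sel_itm"}],"miiv":[{"table":"events","sub_var":"itemid","ids":[50036],"class":"sel_itm"}],"eav_absolute":[{"table":"chartevents","sub_var":"itemid","ids":[90008],"class":"sel_itm"}],"wide_relative":[{"table":"misc","sub_var":"conceptcode","ids":["C90008"],"class":"sel_itm"}],"eav_relative":[{"table":"events","sub_var":"itemid","ids":[90008],"class":"sel_itm"}]}},"tco2":{"class":"num_cncpt","description":"total carbon dioxide","category":"blood gas","unit":["mEq/L"],"min":0,"max":80,"target":"ts_tbl","sources":{"mimic":[{"table":"events","sub_var":"itemid","ids":[50037],"class":"sel_itm"}],"eicu":[{"table":"events","sub_var":"itemid","ids":[50038],"class":"sel_itm"}],"aumc":[{"table":"events","sub_var":"itemid","ids":[50039],"class":"sel_itm"}],"hirid":[{"table":"events","sub_var":"itemid","ids":[50040],"class":"sel_itm"}],"miiv":[{"table":"events","sub_var":"itemid","ids":[50041],"class":"sel_itm"}],"eav_absolute":[{"table":"chartevents","sub_var":"itemid","ids":[90009],"class":"sel_itm"}],"wide_relative":[{"table":"misc","sub_var":"conceptcode","ids":["C90009"],"class":"sel_itm"}],"eav_relative":[{"table":"events","sub_var":"itemid","ids":[90009],"class":"sel_itm"}]}},"pafi":{"class":"rec_cncpt","description":"PaO2/FiO2 ratio","category":"blood gas","concepts":["po2","fio2"],"callback":"pafi_cb","target":"ts_tbl"}}
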