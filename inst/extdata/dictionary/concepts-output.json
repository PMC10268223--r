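{"urine":{"class":"num_cncpt","description":"urine output","category":"output","unit":["mL"],"min":0,"max":2000,"target":"ts_tbl","aggregate":"sum","sources":{"mimic":[{"table":"events","sub_var":"itemid","ids":[50251],"class":"sel_itm"}],"eicu":[{"table":"events","sub_var":"itemid","ids":[50252],"class":"sel_itm"}],"aumc":[{"table":"events","sub_var":"itemid","ids":[50253],"class":"sel_itm"}],"miiv":[{"table":"events","sub_var":"itemid","ids":[50254],"class":"sel_itm"}],"eav_absolute":[{"table":"chartevents","sub_var":"itemid","ids":[90055],"class":"sel_itm"}],"wide_relative":[{"table":"misc","sub_var":"conceptcode","ids":["C90055"],"class":"sel_itm"}],"eav_relative":[{"table":"events","sub_var":"itemid","ids":[90055],"class":"sel_itm"}]}},"urine24":{"class":"rec_cncpt","description":"24-hour urine output","category":"output","concepts":["urine"],"callback":"urine24_cb","target":"ts_tbl"}}
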