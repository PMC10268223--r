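{"egcs":{"class":"num_cncpt","description":"GCS eye component","category":"neurological","min":1,"max":4,"target":"ts_tbl","sources":{"mimic":[{"table":"events","sub_var":"itemid","ids":[50232],"class":"sel_itm"}],"eicu":[{"table":"events","sub_var":"itemid","ids":[50233],"class":"sel_itm"}],"aumc":[{"table":"events","sub_var":"itemid","ids":[50234],"class":"sel_itm"}],"hirid":[{"table":"events","sub_var":"itemid","ids":[50235],"class":"sel_itm"}],"miiv":[{"table":"events","sub_var":"itemid","ids":[50236],"class":"sel_itm"}],"eav_absolute":[{"table":"chartevents","sub_var":"itemid","ids":[220739],"class":"sel_itm"}],"wide_relative":[{"table":"nursecharting","class":"col_itm","value_column":"egcs"}],"eav_relative":[{"table":"events","sub_var":"itemid","ids":[6732],"class":"sel_itm"}]}},"vgcs":{"class":"num_cncpt","description":"GCS verbal component","category":"neurological","min":1,"max":5,"target":"ts_tbl","sources":{"mimic":[{"table":"events","sub_var":"itemid","ids":[50237],"class":"sel_itm"}],"eicu":[{"table":"events","sub_var":"itemid","ids":[50238],"class":"sel_itm"}],"aumc":[{"table":"events","sub_var":"itemid","ids":[50239],"class":"sel_itm"}],"hirid":[{"table":"events","sub_var":"itemid","ids":[50240],"class":"sel_itm"}],"miiv":[{"table":"events","sub_var":"itemid","ids":[50241],"class":"sel_itm"}],"eav_absolute":[{"table":"chartevents","sub_var":"itemid","ids":[223900],"class":"sel_itm"}],"wide_relative":[{"table":"nursecharting","class":"col_itm","value_column":"vgcs"}],"eav_relative":[{"table":"events","sub_var":"itemid","ids":[6735],"class":"sel_itm"}]}},"mgcs":{"class":"num_cncpt","description":"GCS motor component","category":"neurological","min":1,"max":6,"target":"ts_tbl","sources":{"mimic":[{"table":"events","sub_var":"itemid","ids":[50242],"class":"sel_itm"}],"eicu":[{"table":"events","sub_var":"itemid","ids":[50243],"class":"sel_itm"}],"aumc":[{"table":"events","sub_var":"itemid","ids":[50244],"class":"sel_itm"}],"hirid":[{"table":"events","sub_var":"itemid","ids":[50245],"class":"sel_itm"}],"miiv":[{"table":"events","sub_var":"itemid","ids":[50246],"class":"sel_itm"}],"eav_absolute":[{"table":"chartevents","sub_var":"itemid","ids":[223901],"class":"sel_itm"}],"wide_relative":[{"table":"nursecharting","class":"col_itm","value_column":"mgcs"}],"eav_relative":[{"table":"events","sub_var":"itemid","ids":[6734],"class":"sel_itm"}]}},"rass":{"class":"num_cncpt","description":"Richmond agitation-sedation scale","category":"neurological","min":-5,"max":4,"target":"ts_tbl","sources":{"eicu":[{"table":"events","sub_var":"itemid","ids":[50247],"class":"sel_itm"}],"aumc":[{"table":"events","sub_var":"itemid","ids":[50248],"class":"sel_itm"}],"miiv":[{"table":"events","sub_var":"itemid","ids":[50249],"class":"sel_itm"}],"eav_absolute":[{"table":"chartevents","sub_var":"itemid","ids":[90053],"class":"sel_itm"}],"wide_relative":[{"table":"misc","sub_var":"conceptcode","ids":["C90053"],"class":"sel_itm"}],"eav_relative":[{"table":"events","sub_var":"itemid","ids":[90053],"class":"sel_itm"}]}},"avpu":{"class":"fct_cncpt","description":"alert/voice/pain/unresponsive scale","category":"neurological","levels":["A","V","P","U"],"target":"ts_tbl","aggregate":"first","sources":{"eicu":[{"table":"events","sub_var":"itemid","ids":[50250],"class":"sel_itm"}],"eav_absolute":[{"table":"chartevents","sub_var":"itemid","ids":[90054],"class":"sel_itm"}],"wide_relative":[{"table":"misc","sub_var":"conceptcode","ids":["C90054"],"class":"sel_itm"}],"eav_relative":[{"table":"events","sub_var":"itemid","ids":[90054],"class":"sel_itm"}]}},"gcs":{"class":"rec_cncpt","description":"Glasgow coma scale total","category":"neurological","concepts":["egcs","vgcs","mgcs"],"callback":"gcs_cb","target":"ts_tbl","omopid":4093836},"tgcs":{"class":"rec_cncpt","description":"total GCS (alias of component sum)","category":"neurological","concepts":["gcs"],"callback":"tgcs_cb","target":"ts_tbl"}}
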